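# Synthetic left-ventricle cohort generator.
#
# The phantom is a truncated prolate spheroid wall (endocardial sheet,
# epicardial sheet, flat basal cap) with a separable motion model: radial
# contraction about the long axis, longitudinal shortening toward the base,
# and apex-weighted twist, modulated per wall region. Every quantity has an
# analytic or quadrature oracle, which is what makes the downstream pipeline
# testable with known ground truth.

#' Shape parameters of the LV phantom
#'
#' The epicardial surface is a prolate spheroid with equatorial radius
#' `base_radius_mm` and full long axis `long_axis_mm`, truncated by the basal
#' plane that keeps `truncation_fraction` of the long-axis extent; the
#' endocardium is the concentric spheroid offset inward by
#' `wall_thickness_mm`. An optional regional bulge displaces both sheets
#' outward around the direction `bulge_center` (a unit vector in the
#' equatorial plane frame).
#'
#' @param base_radius_mm epicardial equatorial radius (mm).
#' @param long_axis_mm epicardial full long-axis length (mm).
#' @param wall_thickness_mm wall thickness (mm), `< base_radius_mm`.
#' @param truncation_fraction fraction of the spheroid kept below the basal
#'   plane, in (0, 1).
#' @param bulge_amplitude_mm outward bulge amplitude (mm, `>= 0`).
#' @param bulge_center unit direction of the bulge.
#' @param bulge_sigma_rad angular width of the bulge (radians).
#' @param septal_flattening_frac fractional radial flattening of the septal
#'   (-x) side, fixed across the cohort. A real ventricle is not a surface
#'   of revolution (the septum abuts the right ventricle); this breaks the
#'   rotational symmetry of the phantom and makes rigid alignment
#'   well-posed. Set 0 for a pure truncated spheroid.
#' @return object of class `lv_shape_params`.
#' @export
lv_shape_params <- function(base_radius_mm = 33, long_axis_mm = 96,
                            wall_thickness_mm = 8, truncation_fraction = 0.75,
                            bulge_amplitude_mm = 0,
                            bulge_center = c(1, 0, 0),
                            bulge_sigma_rad = 0.55,
                            septal_flattening_frac = 0.10) {
  if (base_radius_mm <= 0 || long_axis_mm <= 0 || wall_thickness_mm <= 0)
    stopf("lengths must be positive")
  if (wall_thickness_mm >= base_radius_mm)
    stopf("wall_thickness_mm (%.3g) must be < base_radius_mm (%.3g)",
          wall_thickness_mm, base_radius_mm)
  if (truncation_fraction <= 0 || truncation_fraction >= 1)
    stopf("truncation_fraction must be in (0,1)")
  if (bulge_amplitude_mm < 0) stopf("bulge_amplitude_mm must be >= 0")
  c_epi <- long_axis_mm / 2
  if (wall_thickness_mm >= c_epi) stopf("wall thicker than the long semi-axis")
  zb <- c_epi * (2 * truncation_fraction - 1)
  if (zb >= c_epi - wall_thickness_mm)
    stopf("basal plane lies above the endocardial extent; reduce truncation")
  structure(list(base_radius_mm = base_radius_mm, long_axis_mm = long_axis_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 truncation_fraction = truncation_fraction,
                 bulge_amplitude_mm = bulge_amplitude_mm,
                 bulge_center = unit_vector(bulge_center),
                 bulge_sigma_rad = bulge_sigma_rad,
                 septal_flattening_frac = septal_flattening_frac),
            class = "lv_shape_params")
}

#' Motion parameters of the LV phantom
#'
#' A separable cyclic motion model. The contraction level p(s) rises from 0
#' at end-diastole (phase 0) to 1 at end-systole (phase = systole fraction)
#' and returns to 0 at phase 1, so frame 0 and frame `n_frames` coincide
#' exactly. Amplitudes are jointly rescaled by a calibration factor so the
#' ejection fraction matches `ef_target`.
#'
#' @param n_frames frames per cardiac cycle.
#' @param ef_target target ejection fraction in (0, 1).
#' @param radial_amplitude fractional radial contraction at p = 1.
#' @param longitudinal_shortening fractional long-axis shortening at p = 1.
#' @param twist_deg peak apical twist (degrees).
#' @param regional_hypokinesia named numeric vector of multiplicative factors
#'   in \[0, 1\] for the radial amplitude per wall region (`"anterior"`,
#'   `"septal"`, `"inferior"`, `"lateral"`).
#' @param phase_profile list with `systole_fraction` (fraction of the cycle
#'   in systole).
#' @return object of class `lv_motion_params`.
#' @export
lv_motion_params <- function(n_frames = 20, ef_target = 0.62,
                             radial_amplitude = 0.25,
                             longitudinal_shortening = 0.15,
                             twist_deg = 12,
                             regional_hypokinesia = numeric(0),
                             phase_profile = list(systole_fraction = 0.35)) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (ef_target <= 0 || ef_target >= 1) stopf("ef_target must be in (0,1)")
  regions <- c("anterior", "septal", "inferior", "lateral")
  if (length(regional_hypokinesia) &&
      (!all(names(regional_hypokinesia) %in% regions) ||
       any(regional_hypokinesia < 0 | regional_hypokinesia > 1)))
    stopf("regional_hypokinesia must map %s to factors in [0,1]",
          paste(regions, collapse = "/"))
  sf <- phase_profile$systole_fraction %||% 0.35
  if (sf <= 0 || sf >= 1) stopf("systole_fraction must be in (0,1)")
  structure(list(n_frames = as.integer(n_frames), ef_target = ef_target,
                 radial_amplitude = radial_amplitude,
                 longitudinal_shortening = longitudinal_shortening,
                 twist_deg = twist_deg,
                 regional_hypokinesia = regional_hypokinesia,
                 phase_profile = list(systole_fraction = sf)),
            class = "lv_motion_params")
}

#' Contraction level at a cycle phase
#'
#' @param motion an [lv_motion_params()].
#' @param s cycle phase in \[0, 1\].
#' @return contraction level p(s) in \[0, 1\]; p(0) = p(1) = 0.
#' @export
phase_contraction <- function(motion, s) {
  sf <- motion$phase_profile$systole_fraction
  s <- s %% 1
  ifelse(s <= sf, 0.5 * (1 - cos(pi * s / sf)),
         0.5 * (1 + cos(pi * (s - sf) / (1 - sf))))
}

#' Generate the LV wall mesh of the phantom
#'
#' Builds a closed, consistently oriented triangulated surface made of an
#' endocardial sheet, an epicardial sheet and a flat basal cap, with
#' per-vertex labels (`"endo"`, `"epi"`, `"base"`). The apex points toward
#' -z; the basal plane is orthogonal to +z.
#'
#' @param shape an [lv_shape_params()].
#' @param resolution number of meridian rings per sheet (`>= 8`); each ring
#'   carries `2 * resolution` vertices.
#' @return a labelled closed [surface_mesh()].
#' @export
generate_lv_mesh <- function(shape, resolution = 24) {
  if (resolution < 8) stopf("resolution must be >= 8")
  c_epi <- shape$long_axis_mm / 2
  r_epi <- shape$base_radius_mm
  c_end <- c_epi - shape$wall_thickness_mm
  r_end <- r_epi - shape$wall_thickness_mm
  zb <- c_epi * (2 * shape$truncation_fraction - 1)
  nphi <- 2 * resolution
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi

  sheet <- function(rr, cc) {
    theta_b <- acos(-zb / cc)
    theta <- theta_b * seq_len(resolution) / resolution
    verts <- matrix(c(0, 0, -cc), 1, 3)
    for (th in theta) {
      ring <- cbind(rr * sin(th) * cos(phi), rr * sin(th) * sin(phi),
                    -cc * cos(th))
      verts <- rbind(verts, ring)
    }
    tris <- NULL
    ring_start <- function(i) 2 + (i - 1) * nphi  # first vertex of ring i
    jn <- c(seq_len(nphi)[-1], 1)
    tris <- cbind(1, ring_start(1) + jn - 1, ring_start(1) + seq_len(nphi) - 1)
    for (i in seq_len(resolution - 1)) {
      a <- ring_start(i) + seq_len(nphi) - 1
      b <- ring_start(i) + jn - 1
      cta <- ring_start(i + 1) + seq_len(nphi) - 1
      ctb <- ring_start(i + 1) + jn - 1
      tris <- rbind(tris, cbind(a, ctb, cta), cbind(a, b, ctb))
    }
    list(vertices = verts, triangles = tris)
  }

  epi <- sheet(r_epi, c_epi)
  endo <- sheet(r_end, c_end)
  # fixed septal flattening: radial compression around the -x direction
  flatten <- function(verts) {
    if (shape$septal_flattening_frac == 0) return(verts)
    phi_v <- atan2(verts[, 2], verts[, 1])
    d <- abs(((phi_v - pi + pi) %% (2 * pi)) - pi)
    w <- exp(-(d / 0.8)^2)
    f <- 1 - shape$septal_flattening_frac * w
    cbind(verts[, 1] * f, verts[, 2] * f, verts[, 3])
  }
  epi$vertices <- flatten(epi$vertices)
  endo$vertices <- flatten(endo$vertices)
  # bulge: outward displacement along the surface direction from the axis
  bulge <- function(verts) {
    if (shape$bulge_amplitude_mm == 0) return(verts)
    dirs <- verts / pmax(sqrt(rowSums(verts^2)), 1e-9)
    ang <- acos(pmin(1, pmax(-1, dirs %*% shape$bulge_center)))
    w <- exp(-(ang / shape$bulge_sigma_rad)^2)
    radial <- verts
    radial[, 3] <- 0
    rn <- sqrt(rowSums(radial^2))
    ok <- rn > 1e-9
    radial[ok, ] <- radial[ok, ] / rn[ok]
    radial[!ok, ] <- 0
    verts + shape$bulge_amplitude_mm * as.vector(w) * radial
  }
  epi$vertices <- bulge(epi$vertices)
  endo$vertices <- bulge(endo$vertices)

  n_epi <- nrow(epi$vertices)
  n_end <- nrow(endo$vertices)
  # base ring between the two rims, labelled "base"
  rim_epi <- (n_epi - nphi + 1):n_epi
  rim_end <- n_epi + ((n_end - nphi + 1):n_end)
  verts <- rbind(epi$vertices, endo$vertices)
  mid <- (verts[rim_epi, , drop = FALSE] + verts[rim_end, , drop = FALSE]) / 2
  mid[, 3] <- zb
  base_idx <- nrow(verts) + seq_len(nphi)
  verts <- rbind(verts, mid)
  # epi outward, endo flipped (outward from the wall points into the cavity)
  tris <- rbind(epi$triangles,
                endo$triangles[, c(1, 3, 2)] + n_epi)
  jn <- c(seq_len(nphi)[-1], 1)
  strip <- function(inner, outer) {
    a <- inner[seq_len(nphi)]
    b <- inner[jn]
    ca <- outer[seq_len(nphi)]
    cb <- outer[jn]
    rbind(cbind(a, b, cb), cbind(a, cb, ca))
  }
  tris <- rbind(tris, strip(rim_epi, base_idx), strip(base_idx, rim_end))
  labels <- c(rep("epi", n_epi), rep("endo", n_end), rep("base", nphi))
  mesh <- surface_mesh(verts, tris, labels)
  if (!is_closed_mesh(mesh)) stopf("internal error: phantom mesh not closed")
  if (signed_mesh_volume(mesh) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

region_weights <- function(phi_angle) {
  centers <- c(anterior = pi / 2, septal = pi, inferior = 3 * pi / 2,
               lateral = 0)
  w <- vapply(centers, function(c0) {
    d <- abs(((phi_angle - c0 + pi) %% (2 * pi)) - pi)
    pmax(0, cos(d / 2))^2
  }, numeric(length(phi_angle)))
  w / pmax(rowSums(w), 1e-12)
}

regional_factor <- function(phi_angle, hypo) {
  f <- c(anterior = 1, septal = 1, inferior = 1, lateral = 1)
  if (length(hypo)) f[names(hypo)] <- hypo
  as.vector(region_weights(phi_angle) %*% f)
}

apply_lv_deformation <- function(mesh, motion, p, alpha, zb, z_apex) {
  if (alpha == 0 || p == 0) return(mesh)
  v <- mesh$vertices
  phi_angle <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  m <- regional_factor(phi_angle, motion$regional_hypokinesia)
  fr <- 1 - alpha * motion$radial_amplitude * p * m
  x <- v[, 1] * fr
  y <- v[, 2] * fr
  z <- zb + (v[, 3] - zb) * (1 - alpha * motion$longitudinal_shortening * p)
  tw <- (pi / 180) * motion$twist_deg * p * (zb - v[, 3]) / (zb - z_apex)
  ct <- cos(tw)
  st <- sin(tw)
  out <- cbind(x * ct - y * st, x * st + y * ct, z)
  surface_mesh(out, mesh$triangles, mesh$vertex_labels)
}

endo_volume_of <- function(mesh) {
  enclosed_volume(endocardial_surface(mesh))
}

calibrate_motion_alpha <- function(mesh, motion, zb, z_apex) {
  v_ed <- endo_volume_of(mesh)
  ef_at <- function(alpha) {
    es <- apply_lv_deformation(mesh, motion, 1, alpha, zb, z_apex)
    1 - endo_volume_of(es) / v_ed
  }
  # physiological cap: no more than 55% radial or longitudinal contraction
  amax <- if (motion$radial_amplitude > 0)
    min(0.55 / motion$radial_amplitude,
        if (motion$longitudinal_shortening > 0)
          0.55 / motion$longitudinal_shortening else Inf)
  else stopf("radial_amplitude must be positive to reach a nonzero EF")
  ef_max <- ef_at(amax)
  if (ef_max < motion$ef_target)
    stopf(paste0("ef_target %.2f unreachable: amplitudes saturate at EF ",
                 "%.2f (raise radial_amplitude/longitudinal_shortening)"),
          motion$ef_target, ef_max)
  uniroot(function(a) ef_at(a) - motion$ef_target, c(0, amax),
          tol = 1e-6)$root
}

#' Deform the phantom mesh through one cardiac cycle
#'
#' Applies the separable motion model at `n_frames` evenly spaced phases.
#' All frames are in vertexwise correspondence with the input; frame 1 (phase
#' 0) is end-diastole (maximal endocardial volume) and the frame nearest the
#' systole fraction is end-systole. Amplitudes are internally rescaled so the
#' realized ejection fraction is within numerical tolerance of `ef_target`.
#'
#' @param mesh a labelled mesh from [generate_lv_mesh()].
#' @param motion an [lv_motion_params()].
#' @return list of `n_frames` [surface_mesh()]; the calibration factor is
#'   attached as attribute `"alpha"` and the endocardial volume trace as
#'   `"volume_trace"`.
#' @export
deform_mesh_sequence <- function(mesh, motion) {
  if (is.null(mesh$vertex_labels))
    stopf("mesh must carry endo/epi/base vertex labels")
  zb <- max(mesh$vertices[, 3])
  z_apex <- min(mesh$vertices[, 3])
  zero_amp <- motion$radial_amplitude == 0 &&
    motion$longitudinal_shortening == 0 && motion$twist_deg == 0
  alpha <- if (zero_amp) 0 else calibrate_motion_alpha(mesh, motion, zb, z_apex)
  s <- (seq_len(motion$n_frames) - 1) / motion$n_frames
  p <- phase_contraction(motion, s)
  frames <- lapply(p, function(pt)
    apply_lv_deformation(mesh, motion, pt, alpha, zb, z_apex))
  attr(frames, "alpha") <- alpha
  attr(frames, "volume_trace") <- vapply(frames, endo_volume_of, numeric(1))
  frames
}

#' Rasterize a mesh sequence into label maps and intensity volumes
#'
#' Builds one grid covering every frame with at least a 2-voxel margin, then
#' per frame rasterizes the closed endocardial (blood pool) and epicardial
#' surfaces into a background / blood-pool / myocardium label map and an
#' intensity image with distinct means per label plus Gaussian noise.
#'
#' @param meshes list of labelled wall meshes (one per frame).
#' @param grid_spacing_mm isotropic voxel size (mm).
#' @param noise_sd intensity noise standard deviation.
#' @param seed RNG seed for the noise (same seed, same volumes).
#' @param intensity_means named means for `background`, `blood`, `myocardium`.
#' @return list with `images` (list of [image_volume()]) and `labels`
#'   (list of [label_map()] with dictionary background=0, blood=1,
#'   myocardium=2).
#' @export
voxelize_subject <- function(meshes, grid_spacing_mm = 1.4, noise_sd = 6,
                             seed = 1,
                             intensity_means = c(background = 50, blood = 180,
                                                 myocardium = 110)) {
  if (grid_spacing_mm <= 0) stopf("spacing must be positive")
  allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  lo <- apply(allv, 2, min) - 2.5 * grid_spacing_mm
  hi <- apply(allv, 2, max) + 2.5 * grid_spacing_mm
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / grid_spacing_mm)) + 1L)
  sp <- rep(grid_spacing_mm, 3)
  dict <- c(background = 0L, blood = 1L, myocardium = 2L)
  images <- vector("list", length(meshes))
  labels <- vector("list", length(meshes))
  rng <- get_rng(seed)
  for (t in seq_along(meshes)) {
    endo <- endocardial_surface(meshes[[t]])
    epi <- epicardial_surface(meshes[[t]])
    tovox <- function(m) sweep(m$vertices, 2, lo) / grid_spacing_mm
    in_endo <- cpp_rasterize(tovox(endo), endo$triangles - 1L, dims)
    in_epi <- cpp_rasterize(tovox(epi), epi$triangles - 1L, dims)
    lab <- array(0L, dims)
    lab[in_epi == 1L] <- 2L
    lab[in_endo == 1L] <- 1L
    mu <- intensity_means[c("background", "blood", "myocardium")]
    img <- array(mu[lab + 1L], dims)
    if (noise_sd > 0) img <- img + rng(rnorm(length(img), 0, noise_sd))
    images[[t]] <- image_volume(img, lo, sp, diag(3))
    labels[[t]] <- label_map(lab, dict, lo, sp, diag(3))
  }
  list(images = images, labels = labels)
}

# run 'expr' under a local RNG stream seeded once; restores global seed
get_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    val <- expr
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    val
  }
}

#' Cohort specification for the synthetic study
#'
#' Defines the study conditions: two groups of subjects sharing a base
#' anatomy and motion pattern, with per-subject shape jitter, per-subject
#' bulge amplitudes (the injected, recoverable shape factor) and group-level
#' motion offsets (the injected, recoverable motion factor; by default the
#' patient group has a hypokinetic septum). The cohort is a pure function of
#' the spec, seed included.
#'
#' @param n_subjects_per_group subjects per group.
#' @param group_motion_offsets named list (one entry per group) of overrides
#'   of [lv_motion_params()] fields.
#' @param shape_jitter_sd named numeric sd of per-subject jitter applied to
#'   `base_radius_mm`, `long_axis_mm`, `wall_thickness_mm`; plus
#'   `bulge_amplitude_mm`, drawn half-normal so it is nonnegative.
#' @param ef_jitter_sd per-subject sd of the EF target.
#' @param base_shape,base_motion cohort-level base parameters.
#' @param grid_spacing_mm,noise_sd,slice_spacing_mm,mesh_resolution imaging
#'   and meshing conditions.
#' @param seed integer seed; same seed gives a bit-identical cohort.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_subjects_per_group = 4,
                                  group_motion_offsets = list(
                                    control = list(),
                                    AS = list(regional_hypokinesia =
                                                c(septal = 0.05,
                                                  inferior = 0.4),
                                              twist_deg = 4)),
                                  shape_jitter_sd = c(base_radius_mm = 0.25,
                                                      long_axis_mm = 0.6,
                                                      wall_thickness_mm = 0.12,
                                                      bulge_amplitude_mm = 6),
                                  ef_jitter_sd = 0.012,
                                  base_shape = lv_shape_params(),
                                  base_motion = lv_motion_params(),
                                  grid_spacing_mm = 1.4, noise_sd = 6,
                                  slice_spacing_mm = 8, mesh_resolution = 24,
                                  seed = 1) {
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 group_motion_offsets = group_motion_offsets,
                 shape_jitter_sd = shape_jitter_sd,
                 ef_jitter_sd = ef_jitter_sd,
                 base_shape = base_shape, base_motion = base_motion,
                 grid_spacing_mm = grid_spacing_mm, noise_sd = noise_sd,
                 slice_spacing_mm = slice_spacing_mm,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

jitter_shape <- function(base, sd, draw, bulge_quantile = NULL) {
  # bulge amplitudes are stratified across the cohort (one half-normal
  # quantile stratum per subject, jittered): at the small cohort sizes of
  # the recovery experiments an iid draw routinely produces near-tied
  # amplitudes, which makes rank recovery ill-posed by construction
  bulge <- if (!is.null(bulge_quantile)) {
    s <- if (is.na(sd["bulge_amplitude_mm"])) 0 else sd[["bulge_amplitude_mm"]]
    base$bulge_amplitude_mm + s * stats::qnorm((1 + bulge_quantile) / 2)
  } else {
    abs(base$bulge_amplitude_mm + draw("bulge_amplitude_mm", sd))
  }
  args <- list(base_radius_mm = base$base_radius_mm +
                 draw("base_radius_mm", sd),
               long_axis_mm = base$long_axis_mm + draw("long_axis_mm", sd),
               wall_thickness_mm = base$wall_thickness_mm +
                 draw("wall_thickness_mm", sd),
               truncation_fraction = base$truncation_fraction,
               bulge_amplitude_mm = bulge,
               bulge_center = base$bulge_center,
               bulge_sigma_rad = base$bulge_sigma_rad,
               septal_flattening_frac = base$septal_flattening_frac)
  do.call(lv_shape_params, args)
}

#' Generate the full synthetic cohort
#'
#' For each subject: ground-truth wall meshes over the cycle, per-frame label
#' maps and intensity volumes, a whole-heart volume taken at the end-diastolic
#' (mid-diastolic rest) frame, a short-axis cine stack, and the true shape and
#' motion parameters. Deterministic given the spec.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param voxelize generate images and cine stacks (set `FALSE` for a fast
#'   meshes-plus-ground-truth-only cohort; the mesh draws are identical
#'   either way).
#' @return a cohort bundle: list with `spec` and `subjects`, each subject a
#'   list with `id`, `group`, `seed`, `shape`, `motion`, `meshes`, `labels`,
#'   `images`, `wh`, `wh_labels`, `cine`, `volume_trace`, `edv_ml`, `ef`.
#' @export
generate_cohort <- function(spec, voxelize = TRUE) {
  groups <- names(spec$group_motion_offsets)
  n_total <- length(groups) * spec$n_subjects_per_group
  # stratified bulge quantiles, assigned to subjects by a seeded permutation
  perm_rng <- get_rng(spec$seed * 1009L + 17L)
  strata <- perm_rng(sample(n_total))
  jit <- perm_rng(runif(n_total, 0.2, 0.8))
  bulge_q <- (strata - jit) / n_total
  subjects <- list()
  idx <- 0
  for (g in groups) {
    for (i in seq_len(spec$n_subjects_per_group)) {
      idx <- idx + 1
      sseed <- spec$seed * 1009L + idx * 131L
      rng <- get_rng(sseed)
      draw <- function(field, sd)
        if (is.na(sd[field]) || is.null(sd[field])) 0 else
          rng(rnorm(1, 0, sd[[field]]))
      shape <- jitter_shape(spec$base_shape, spec$shape_jitter_sd, draw,
                            bulge_quantile = bulge_q[idx])
      margs <- unclass(spec$base_motion)
      for (nm in names(spec$group_motion_offsets[[g]]))
        margs[[nm]] <- spec$group_motion_offsets[[g]][[nm]]
      margs$ef_target <- min(0.85, max(0.35, margs$ef_target +
                                         rng(rnorm(1, 0, spec$ef_jitter_sd))))
      motion <- do.call(lv_motion_params, margs)
      mesh <- generate_lv_mesh(shape, spec$mesh_resolution)
      frames <- deform_mesh_sequence(mesh, motion)
      trace <- attr(frames, "volume_trace")
      subj <- list(id = sprintf("%s_%d", g, i), group = g,
                   seed = sseed, shape = shape, motion = motion,
                   meshes = frames, volume_trace = trace,
                   edv_ml = max(trace) / 1000,
                   ef = 1 - min(trace) / max(trace))
      if (voxelize) {
        vox <- voxelize_subject(frames, spec$grid_spacing_mm, spec$noise_sd,
                                seed = sseed + 7L)
        subj$labels <- vox$labels
        subj$images <- vox$images
        subj$wh <- vox$images[[1]]
        subj$wh_labels <- vox$labels[[1]]
        subj$cine <- make_cine_stack(vox$images, spec$slice_spacing_mm)
      }
      subjects[[idx]] <- subj
    }
  }
  list(spec = spec, subjects = subjects)
}

#' Write a cohort bundle to disk
#'
#' One directory per subject: whole-heart NIfTI at the end-diastolic frame,
#' its label map, the cine stack with JSON manifest, ground-truth meshes
#' (VTK) and a YAML record of the true parameters; plus a cohort-level
#' `cohort.yaml` manifest with group labels and seeds.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$spec$seed, subjects = list())
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_volume(s$wh, file.path(sd, "wh.nii.gz"))
    write_volume(s$wh_labels, file.path(sd, "wh_seg.nii.gz"))
    write_cine_stack(s$cine, file.path(sd, "cine"))
    for (t in seq_along(s$meshes))
      write_mesh(s$meshes[[t]], file.path(sd, sprintf("gt_frame%02d.vtk", t)))
    truth <- list(id = s$id, group = s$group, seed = s$seed,
                  shape = unclass(s$shape)[
                    c("base_radius_mm", "long_axis_mm", "wall_thickness_mm",
                      "truncation_fraction", "bulge_amplitude_mm")],
                  ef_target = s$motion$ef_target,
                  regional_hypokinesia =
                    as.list(s$motion$regional_hypokinesia),
                  edv_ml = s$edv_ml, ef = s$ef,
                  volume_trace_mm3 = s$volume_trace)
    yaml::write_yaml(truth, file.path(sd, "truth.yaml"))
    manifest$subjects[[length(manifest$subjects) + 1]] <-
      list(id = s$id, group = s$group, seed = s$seed)
  }
  yaml::write_yaml(manifest, file.path(dir, "cohort.yaml"))
  invisible(dir)
}
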