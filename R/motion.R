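# Motion analysis decoupled from shape: subject-specific deformations are
# replayed on a population-average carrier shape (the SuperTemplate), so the
# pooled shapes differ only by motion; the SSA machinery then yields motion
# modes and per-subject motion-vector time traces.

#' Population SuperTemplate from the subject templates
#'
#' The average shape of the (scaled, aligned) subject templates: by default
#' the template of an atlas estimated over them; with `method = "mean"`, the
#' vertexwise mean (requires a shared topology).
#'
#' @param subject_templates list of subject template [surface_mesh()]s.
#' @param kernel [kernel_params()] for the atlas route.
#' @param method `"atlas"` or `"mean"`.
#' @param n_control_points,opt_params passed to [estimate_atlas()].
#' @return the SuperTemplate [surface_mesh()].
#' @export
compute_supertemplate <- function(subject_templates, kernel,
                                  method = c("atlas", "mean"),
                                  n_control_points = 125,
                                  opt_params = list()) {
  method <- match.arg(method)
  if (method == "mean") {
    same <- all(vapply(subject_templates, function(m)
      identical(dim(m$vertices), dim(subject_templates[[1]]$vertices)),
      logical(1)))
    if (!same) stopf("method 'mean' requires a shared topology")
    vm <- Reduce(`+`, lapply(subject_templates, function(m) m$vertices)) /
      length(subject_templates)
    return(surface_mesh(vm, subject_templates[[1]]$triangles,
                        subject_templates[[1]]$vertex_labels))
  }
  atlas <- estimate_atlas(subject_templates, kernel, n_control_points,
                          opt_params)
  atlas$template
}

#' Replay a subject's per-frame deformations on the SuperTemplate
#'
#' Flows the SuperTemplate with the subject's own momenta and (transformed)
#' control points for every frame, producing the subject's contraction
#' pattern applied to a neutral shape.
#'
#' @param supertemplate the carrier [surface_mesh()].
#' @param model subject [anatomical_model()] already in the common space.
#' @return list of `n_frames` [surface_mesh()]s.
#' @export
transfer_motion <- function(supertemplate, model) {
  lapply(model$momenta, function(b)
    flow(supertemplate, model$control_points, b, model$kernel))
}

#' Motion analysis over the pooled shape-free frame meshes
#'
#' Pools the transferred frames of all subjects (n_subjects x n_frames
#' shapes), estimates one motion model over the pool (template fixed to the
#' SuperTemplate by default; set `fix_template = FALSE` to re-estimate it),
#' fits PCA on the pooled momenta, and returns per-subject motion traces
#' (projections ordered by frame, phase = fraction of the RR interval) plus
#' +/- 2 sigma motion-mode meshes with per-vertex displacement ("arrow")
#' fields.
#'
#' @param supertemplate the carrier [surface_mesh()].
#' @param models per-subject [anatomical_model()]s in the common space.
#' @param kernel [kernel_params()] for the pooled motion model.
#' @param n_modes modes to report; default reaches 75% cumulative variance.
#' @param fix_template keep the SuperTemplate as the pooled model's template.
#' @param n_control_points,opt_params optimization settings.
#' @param subject_ids optional subject ids.
#' @return list with `pca`, `traces` (data frame: subject_id, frame, phase,
#'   mode_*), `mode_meshes`, `arrow_fields` (per mode, per-vertex
#'   displacement vectors from the template), `model`.
#' @export
run_motion_analysis <- function(supertemplate, models, kernel,
                                n_modes = NULL, fix_template = TRUE,
                                n_control_points = 125, opt_params = list(),
                                subject_ids = NULL) {
  if (length(models) < 2) stopf("need at least 2 subjects")
  ids <- subject_ids %||% vapply(seq_along(models), function(i)
    models[[i]]$provenance$subject_id %||% sprintf("subject_%d", i),
    character(1))
  n_frames <- vapply(models, function(m) length(m$momenta), integer(1))
  pooled <- list()
  for (i in seq_along(models))
    pooled <- c(pooled, transfer_motion(supertemplate, models[[i]]))
  opt <- default_opt_params(opt_params)
  if (fix_template) {
    cp <- control_point_grid(supertemplate, n_control_points)
    momenta <- vector("list", length(pooled))
    ro <- opt
    ro$max_iter <- opt$reg_iters
    subj_of <- rep(seq_along(models), n_frames)
    for (j in seq_along(pooled)) {
      # frames are consecutive within a subject: warm-start each frame's
      # momenta from its predecessor (reset at subject boundaries, so every
      # subject's momenta follow the same optimization path and no
      # subject-specific representation leaks into the pooled coordinates)
      ro$init_momenta <- if (j > 1 && subj_of[j] == subj_of[j - 1])
        momenta[[j - 1]] else NULL
      momenta[[j]] <- unclass(estimate_registration(supertemplate,
                                                    pooled[[j]], cp, kernel,
                                                    ro))
    }
    model <- anatomical_model(supertemplate, cp, momenta, kernel,
                              provenance = list(pooled = length(pooled)))
  } else {
    model <- estimate_atlas(pooled, kernel, n_control_points, opt_params)
  }
  pca <- fit_pca(stack_momenta(model$momenta))
  nm <- default_mode_count(pca, n_modes)
  rows <- list()
  j <- 0
  for (i in seq_along(models)) {
    for (t in seq_len(n_frames[i])) {
      j <- j + 1
      cf <- project(model$momenta[[j]], pca)[seq_len(nm)]
      rows[[j]] <- data.frame(subject_id = ids[i], frame = t,
                              phase = (t - 1) / n_frames[i],
                              t(as.matrix(cf)))
    }
  }
  traces <- do.call(rbind, rows)
  names(traces)[-(1:3)] <- paste0("mode_", seq_len(nm))
  mode_meshes <- list()
  arrow_fields <- list()
  tmpl <- model$template
  for (m in seq_len(nm)) {
    plus <- mode_mesh(tmpl, model$control_points, pca, m, 2, model$kernel)
    minus <- mode_mesh(tmpl, model$control_points, pca, m, -2, model$kernel)
    mode_meshes[[m]] <- list(plus = plus, minus = minus)
    arrow_fields[[m]] <- list(plus = plus$vertices - tmpl$vertices,
                              minus = minus$vertices - tmpl$vertices)
  }
  list(pca = pca, traces = traces, mode_meshes = mode_meshes,
       arrow_fields = arrow_fields, model = model)
}

#' Tile motion traces over several cardiac cycles for plotting
#'
#' @param traces trace data frame from [run_motion_analysis()].
#' @param n_cycles number of cycles to tile (>= 1).
#' @return data frame with a continuous `phase` axis over `n_cycles` cycles.
#' @export
export_trace_plot_data <- function(traces, n_cycles) {
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  out <- NULL
  for (c in seq_len(n_cycles)) {
    t2 <- traces
    t2$phase <- t2$phase + (c - 1)
    t2$cycle <- c
    out <- rbind(out, t2)
  }
  out[order(out$subject_id, out$phase), , drop = FALSE]
}
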