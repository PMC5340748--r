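#' Write / read a CSV table with exact float round-trip
#'
#' Floats are serialized with 17 significant digits so that
#' `read_table(write_table(x))` reproduces every double bit-exactly. `rows`
#' may be a data frame or a list of equal-length rows; ragged rows raise an
#' error.
#'
#' @param rows data frame, or list of named equal-length vectors/lists.
#' @param path output CSV path.
#' @return `path` invisibly; `read_table()` returns a data frame.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows) || length(rows) == 0)
      stopf("rows must be a non-empty data frame or list of rows")
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1) stopf("ragged rows: lengths %s",
                                         paste(unique(lens), collapse = ", "))
    nms <- names(rows[[1]])
    if (!is.null(nms) &&
        !all(vapply(rows, function(r) identical(names(r), nms), logical(1))))
      stopf("ragged rows: inconsistent column names")
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(r), stringsAsFactors = FALSE)))
  }
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stopf("table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df
}
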