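#' Write microtubule-end traces to CSV
#'
#' One row per trace point, columns `end_id`, `pf_id`, `point_index`
#' (0-based, contiguous), `x_nm`, `y_nm`, `z_nm`, plus optional `condition`
#' and `length_um` carried per end. Rows are ordered by end id,
#' protofilament id, then point index, so output bytes are deterministic
#' for a fixed input.
#'
#' @param ends A list of [mt_end()] objects (non-empty).
#' @param path Output CSV path.
#' @export
write_traces <- function(ends, path) {
  if (inherits(ends, "mt_end")) ends <- list(ends)
  if (!length(ends) || !all(vapply(ends, inherits, TRUE, "mt_end")))
    stop("`ends` must be a non-empty list of mt_end objects", call. = FALSE)
  rows <- lapply(ends, function(e) {
    do.call(rbind, lapply(e$traces, function(tr) {
      n <- nrow(tr$points)
      data.frame(end_id = e$end_id, pf_id = tr$pf_id,
                 point_index = seq_len(n) - 1L,
                 x_nm = tr$points[, 1], y_nm = tr$points[, 2],
                 z_nm = tr$points[, 3],
                 condition = e$condition, length_um = e$length_um)
    }))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$end_id, tab$pf_id, tab$point_index), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read microtubule-end traces from CSV
#'
#' Inverse of [write_traces()]. Coordinates are taken as nm. Point indices
#' must be contiguous from 0 within each (end, protofilament); violations
#' and non-finite coordinates are reported with the offending ids.
#'
#' @param path CSV path.
#' @return A list of [mt_end()] objects, one per `end_id`, traces sorted by
#'   `pf_id`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("end_id", "pf_id", "point_index", "x_nm", "y_nm", "z_nm")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  coords <- as.matrix(tab[, c("x_nm", "y_nm", "z_nm")])
  if (any(!is.finite(coords))) {
    bad <- which(!is.finite(coords), arr.ind = TRUE)[1, 1]
    stop(sprintf("non-finite coordinate at row %d (end %s, pf %s)",
                 bad, tab$end_id[bad], tab$pf_id[bad]), call. = FALSE)
  }
  ends <- lapply(split(tab, tab$end_id), function(sub) {
    traces <- lapply(split(sub, sub$pf_id), function(pf) {
      pf <- pf[order(pf$point_index), , drop = FALSE]
      if (!identical(as.integer(pf$point_index),
                     seq_len(nrow(pf)) - 1L))
        stop(sprintf("non-contiguous point_index for end %s, pf %d",
                     pf$end_id[1], pf$pf_id[1]), call. = FALSE)
      pf_trace(pf$end_id[1], pf$pf_id[1],
               as.matrix(pf[, c("x_nm", "y_nm", "z_nm")]))
    })
    mt_end(sub$end_id[1], traces,
           condition = if ("condition" %in% names(sub))
             sub$condition[1] else NA_character_,
           length_um = if ("length_um" %in% names(sub))
             sub$length_um[1] else NA_real_)
  })
  ends[order(names(ends))]
}
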