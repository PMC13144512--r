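#' Assemble a result bundle
#'
#' A container for pipeline outputs: per-end summaries, per-protofilament
#' measurements, cluster and sweep tables, fluorescence measurements, and
#' provenance (seed, configuration echo, package version).
#'
#' @param ... Named result components (data frames or lists).
#' @param seed Seed the run was performed with.
#' @param config Configuration echo (list).
#' @return An object of class `result_bundle`.
#' @export
result_bundle <- function(..., seed = NA_integer_, config = list()) {
  parts <- list(...)
  if (length(parts) && (is.null(names(parts)) || any(names(parts) == "")))
    stop("all bundle components must be named", call. = FALSE)
  structure(c(parts,
              list(provenance = list(
                seed = seed, config = config,
                package = "mtflare",
                version = as.character(utils::packageVersion("mtflare"))))),
            class = "result_bundle")
}

#' Write a result bundle to JSON
#'
#' Numbers are serialised at full precision and keys keep their insertion
#' order, so output bytes are stable for a fixed bundle.
#'
#' @param bundle A [result_bundle()].
#' @param path Output JSON path.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a result bundle back from JSON
#'
#' @param path JSON path written by [write_results()].
#' @return A `result_bundle`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "result_bundle")
}
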