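#' Write a kymograph as TIFF with a JSON sidecar
#'
#' The intensity array is stored as a single-channel 32-bit TIFF (rows =
#' time, columns = position). TIFF storage is normalised to \[0, 1\]; the
#' scale and offset, together with the pixel size and frame interval, go
#' into a JSON sidecar with the same basename (`.json`), from which
#' [read_kymograph()] restores the original values.
#'
#' @param kymo A [kymograph()].
#' @param path Output TIFF path.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 32L)
  meta <- list(pixel_nm = kymo$pixel_nm, frame_s = kymo$frame_s,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a kymograph TIFF with its JSON sidecar
#'
#' @param path TIFF path; pixel size and frame interval are read from the
#'   JSON sidecar written by [write_kymograph()], never from TIFF tags.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar ", side,
         ": supply pixel_nm and frame_s in a JSON sidecar", call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$pixel_nm) || is.null(meta$frame_s))
    stop("sidecar must supply pixel_nm and frame_s", call. = FALSE)
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("unsupported format: multi-channel TIFF", call. = FALSE)
    img <- img[, , 1L]
  }
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% 1
  kymograph(img * sc + off, meta$pixel_nm, meta$frame_s)
}
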