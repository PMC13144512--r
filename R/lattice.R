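#' Microtubule lattice model
#'
#' Describes the intact cylindrical lattice of a microtubule: the number of
#' protofilaments, the radius of the cylinder through the protofilament
#' centres, and the axial tubulin-monomer repeat (about 4.1 nm in
#' GDP-lattice microtubules). The reference lateral spacing between
#' neighbouring protofilaments is the chord
#' \eqn{d_{ref} = 2 R \sin(\pi / n_{pf})}.
#'
#' @param n_pf Number of protofilaments (>= 2). Default 13, the canonical
#'   in-vivo protofilament number.
#' @param radius_nm Radius (nm) of the cylinder through protofilament
#'   centres. Default 11.
#' @param monomer_spacing_nm Axial tubulin-monomer repeat (nm). Default 4.1.
#' @param helix_rise_nm Per-protofilament axial offset of the 3-start helix
#'   (nm). Default `3 * monomer_spacing_nm / n_pf`.
#' @return An object of class `lattice_model`.
#' @examples
#' lat <- lattice_model()
#' d_ref(lat)  # ~5.29 nm lateral neighbour spacing
#' @export
lattice_model <- function(n_pf = 13L, radius_nm = 11.0,
                          monomer_spacing_nm = 4.1,
                          helix_rise_nm = 3 * monomer_spacing_nm / n_pf) {
  check_scalar(n_pf, "n_pf", integerish = TRUE)
  if (n_pf < 2) stop_field("n_pf", "must be >= 2")
  check_scalar(radius_nm, "radius_nm", positive = TRUE)
  check_scalar(monomer_spacing_nm, "monomer_spacing_nm", positive = TRUE)
  check_scalar(helix_rise_nm, "helix_rise_nm", nonneg = TRUE)
  structure(list(n_pf = as.integer(n_pf), radius_nm = radius_nm,
                 monomer_spacing_nm = monomer_spacing_nm,
                 helix_rise_nm = helix_rise_nm),
            class = "lattice_model")
}

#' Reference lateral neighbour distance of a lattice
#'
#' Chord distance between adjacent protofilament centres,
#' \eqn{2 R \sin(\pi / n_{pf})}.
#'
#' @param lattice A [lattice_model()], or a fitted `axis_model` carrying a
#'   radius, in which case `n_pf` must be supplied.
#' @param n_pf Protofilament count when `lattice` is an `axis_model`.
#' @return Distance in nm.
#' @export
d_ref <- function(lattice, n_pf = NULL) {
  if (inherits(lattice, "lattice_model")) {
    r <- lattice$radius_nm
    n <- lattice$n_pf
  } else if (inherits(lattice, "axis_model")) {
    r <- lattice$radius_nm
    n <- n_pf %||% stop_field("n_pf", "required with an axis_model")
  } else stop("`lattice` must be a lattice_model or axis_model", call. = FALSE)
  2 * r * sin(pi / n)
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf(
    "<lattice_model> %d protofilaments, radius %.2f nm, repeat %.2f nm (d_ref %.2f nm)\n",
    x$n_pf, x$radius_nm, x$monomer_spacing_nm, d_ref(x)))
  invisible(x)
}
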