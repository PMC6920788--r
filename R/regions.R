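#' Radial region decomposition around the protein
#'
#' The membrane around the protein wall at `r = Rp` is partitioned into
#' annular regions by the ordered-domain radii `Rd` (inner leaflet) and `Ru`
#' (outer leaflet).  Within each region the unperturbed thickness of each
#' leaflet is constant: the outer leaflet is ordered (thickness `h_r`) for
#' `r < Ru` and disordered (`h_s`) beyond, and likewise the inner leaflet
#' relative to `Rd`.  Coincident radii collapse the corresponding region.
#'
#' @param params `membrane_params`.
#' @param geom `protein_geometry`.
#' @param conf `domain_configuration`.
#' @param tol radii closer than this are considered coincident (nm).
#' @return a data.frame with one row per region and columns `r_in`, `r_out`
#'   (`Inf` for the unbounded outermost region), `h0_upper`, `h0_lower`.
#' @export
build_regions <- function(params, geom, conf, tol = 1e-9) {
  Rp <- geom$Rp
  bounds <- sort(unique(c(Rp, conf$Rd, conf$Ru)))
  bounds <- bounds[c(TRUE, diff(bounds) > tol)]
  r_in <- bounds
  r_out <- c(bounds[-1], Inf)
  mid <- ifelse(is.finite(r_out), (r_in + r_out) / 2, r_in + 1)
  data.frame(
    r_in = r_in, r_out = r_out,
    h0_upper = ifelse(mid < conf$Ru, params$h_r, params$h_s),
    h0_lower = ifelse(mid < conf$Rd, params$h_r, params$h_s)
  )
}
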