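#' Reference physical parameter set
#'
#' Builds the set of elastic and thermodynamic parameters of the membrane
#' model, starting from the reference values for model "raft" lipid mixtures
#' and applying any overrides.  All quantities are in model units: lengths in
#' nm, energies in kBT0 (thermal energy at the reference temperature T0 ~
#' 300 K, kBT0 ~ 4.14e-21 J), so `kT = 1` at the reference temperature.
#'
#' Fields:
#' \describe{
#'   \item{B}{monolayer bending (splay) modulus, kBT0. Default 10.}
#'   \item{K}{monolayer tilt modulus, kBT0/nm^2. Default 10 (= 40 mN/m).}
#'   \item{sigma}{monolayer lateral tension, kBT0/nm^2. Default 0.01.}
#'   \item{h_r}{equilibrium thickness of the liquid-ordered monolayer, nm.
#'     Default 1.8.}
#'   \item{h_s}{equilibrium thickness of the disordered (surrounding)
#'     monolayer, nm. Default 1.3.}
#'   \item{a_qm}{area per quasimolecule (the Slezov exchange unit containing
#'     all lipid components in the domain stoichiometry), nm^2. Default 0.5,
#'     a typical ordered-phase area per lipid; equilibrium domain sizes
#'     depend on the ratio Delta/a_qm, so this is a first-class knob.}
#'   \item{Delta}{subsaturation, dimensionless deviation of the composition
#'     from the phase-separation point. Default 0.01 (1 percent).}
#'   \item{kT}{thermal energy in kBT0 units. Default 1.}
#' }
#'
#' @param overrides named list (or named arguments via `...`) of field
#'   values replacing the defaults.
#' @param ... individual overrides, alternative to `overrides`.
#' @return an object of class `membrane_params` (a validated named list).
#' @examples
#' make_params()
#' make_params(Delta = 0)
#' @export
make_params <- function(overrides = list(), ...) {
  defaults <- list(
    B = 10, K = 10, sigma = 0.01,
    h_r = 1.8, h_s = 1.3,
    a_qm = 0.5, Delta = 0.01, kT = 1
  )
  dots <- list(...)
  overrides <- c(overrides, dots)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("configuration error: all parameter overrides must be named",
           call. = FALSE)
    }
    bad <- setdiff(nm, names(defaults))
    if (length(bad)) {
      stop("configuration error: unknown parameter field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  p <- structure(defaults, class = "membrane_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("B", "K", "sigma", "h_r", "h_s", "a_qm", "kT")) {
    if (!num1(p[[f]]) || p[[f]] <= 0) {
      stop("validation error: field '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (!num1(p$Delta) || p$Delta < 0) {
    stop("validation error: field 'Delta' must be a non-negative number",
         call. = FALSE)
  }
  if (p$h_r < p$h_s) {
    stop("validation error: field 'h_r' must satisfy h_r >= h_s ",
         "(the ordered phase cannot be thinner than the disordered one)",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane model parameters (nm, kBT0 units)\n")
  cat(sprintf("  bending modulus        B     = %g kBT0\n", x$B))
  cat(sprintf("  tilt modulus           K     = %g kBT0/nm^2\n", x$K))
  cat(sprintf("  lateral tension        sigma = %g kBT0/nm^2\n", x$sigma))
  cat(sprintf("  ordered thickness      h_r   = %g nm\n", x$h_r))
  cat(sprintf("  disordered thickness   h_s   = %g nm\n", x$h_s))
  cat(sprintf("  area per quasimolecule a_qm  = %g nm^2\n", x$a_qm))
  cat(sprintf("  subsaturation          Delta = %g\n", x$Delta))
  cat(sprintf("  thermal energy         kT    = %g kBT0\n", x$kT))
  invisible(x)
}

#' Transmembrane-domain geometry
#'
#' Describes the rigid cylindrical transmembrane domain (TMD): its radius,
#' hydrophobic length, and the radial projections of the boundary directors
#' it imposes on the two leaflets.  The sign convention is that a positive
#' radial projection points away from the protein axis in \emph{both}
#' leaflets, so `n1 > 0, n2 > 0` is a barrel-like TMD and
#' `n1 < 0, n2 < 0` an hourglass.
#'
#' @param Rp TMD radius in the membrane plane, nm (> 0).
#' @param Hp TMD hydrophobic length, nm (> 0).
#' @param n1 radial boundary-director projection in the outer (upper)
#'   leaflet, dimensionless, |n1| <= 0.7 (small-deformation validity range).
#' @param n2 same for the inner (lower) leaflet.
#' @return an object of class `protein_geometry`.
#' @seealso [egfr_geometry()] for the EGFR conformational presets.
#' @export
protein_geometry <- function(Rp, Hp, n1 = 0, n2 = 0) {
  g <- structure(list(Rp = Rp, Hp = Hp, n1 = n1, n2 = n2),
                 class = "protein_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(g$Rp) || g$Rp <= 0) {
    stop("validation error: field 'Rp' must be a positive number", call. = FALSE)
  }
  if (!num1(g$Hp) || g$Hp <= 0) {
    stop("validation error: field 'Hp' must be a positive number", call. = FALSE)
  }
  for (f in c("n1", "n2")) {
    if (!num1(g[[f]]) || abs(g[[f]]) > 0.7 + 1e-12) {
      stop("validation error: field '", f, "' must lie in [-0.7, 0.7] ",
           "(small-deformation validity range)", call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.protein_geometry <- function(x, ...) {
  cat("Transmembrane-domain geometry\n")
  cat(sprintf("  radius Rp = %g nm, hydrophobic length Hp = %g nm\n",
              x$Rp, x$Hp))
  cat(sprintf("  boundary directors: outer n1 = %+g, inner n2 = %+g\n",
              x$n1, x$n2))
  invisible(x)
}

#' EGFR transmembrane-domain conformation presets
#'
#' The epidermal growth factor receptor TMD dimer switches between an
#' inactive (closed) and an active (open) conformation; the effective TMD
#' radius increases from about 0.9 nm to 1.6 nm on opening.  The hydrophobic
#' length is set to twice the ordered-monolayer thickness (`Hp = 2 h_r`), i.e.
#' zero hydrophobic mismatch between the protein and the ordered phase.
#'
#' @param conformation `"closed"` (Rp = 0.9 nm) or `"open"` (Rp = 1.6 nm).
#' @param n1,n2 boundary-director radial projections (see
#'   [protein_geometry()]). Characteristic values: closed n1 < 0, n2 ~ 0;
#'   open n1 > 0, n2 < 0.
#' @param params a `membrane_params` object (supplies h_r).
#' @return a `protein_geometry` object.
#' @examples
#' egfr_geometry("closed", n1 = -0.3, n2 = 0)
#' @export
egfr_geometry <- function(conformation = c("closed", "open"),
                          n1 = 0, n2 = 0, params = make_params()) {
  if (!is.character(conformation) || length(conformation) != 1L ||
      !conformation %in% c("closed", "open")) {
    stop("unknown conformation label; must be \"closed\" or \"open\"",
         call. = FALSE)
  }
  Rp <- if (conformation == "closed") 0.9 else 1.6
  protein_geometry(Rp = Rp, Hp = 2 * params$h_r, n1 = n1, n2 = n2)
}

#' Ordered-domain configuration
#'
#' Radii of the liquid-ordered annuli in the two leaflets.  A radius equal
#' to the protein radius `Rp` means no ordered annulus in that leaflet.
#'
#' @param Rd ordered-domain radius in the inner (lower) leaflet, nm, >= Rp.
#' @param Ru ordered-domain radius in the outer (upper) leaflet, nm, >= Rp.
#' @param geom the `protein_geometry` the configuration refers to.
#' @return an object of class `domain_configuration` with derived widths
#'   `L_d = Rd - Rp` and `L_u = Ru - Rp`.
#' @export
domain_configuration <- function(Rd, Ru, geom) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(Rd) || !num1(Ru)) {
    stop("validation error: 'Rd' and 'Ru' must be finite numbers",
         call. = FALSE)
  }
  if (Rd < geom$Rp - 1e-9 || Ru < geom$Rp - 1e-9) {
    stop("validation error: domain radii 'Rd' and 'Ru' must be >= Rp",
         call. = FALSE)
  }
  structure(list(Rd = max(Rd, geom$Rp), Ru = max(Ru, geom$Rp),
                 Rp = geom$Rp,
                 L_d = max(Rd - geom$Rp, 0), L_u = max(Ru - geom$Rp, 0)),
            class = "domain_configuration")
}

#' @export
print.domain_configuration <- function(x, ...) {
  cat(sprintf(
    "Ordered-domain configuration: Ru = %g nm (L_u = %g), Rd = %g nm (L_d = %g)\n",
    x$Ru, x$L_u, x$Rd, x$L_d))
  invisible(x)
}
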