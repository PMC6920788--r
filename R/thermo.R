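# Wetting thermodynamics: elastic grand-potential curves -> chemical
# potential and total free energy under subsaturation -> equilibria.
#
# The ordered domain exchanges "quasimolecules" (Slezov exchange units of
# area a_qm) with the surrounding membrane.  With the chemical potential
# normalized to zero for an infinite domain, mu(s) = a_qm * dW/ds, the
# equilibrium condition is mu = -kT * Delta, and the total free energy of a
# domain of area s is E(s) = W(s) - W(s0) + kT*Delta*(s - s0)/a_qm, whose
# interior minima are the (meta)stable domains.

#' Elastic grand-potential curve
#'
#' Container for W sampled against domain size, either the total ordered
#' area `s` (bilayer subsaturation) or the inner-domain radius `r`
#' (monolayer subsaturation, where only the inner-leaflet area exchanges
#' with the subsaturated reservoir).
#'
#' @param x abscissa samples, strictly increasing: area (nm^2) or inner
#'   radius (nm).
#' @param W elastic grand potential at the samples (kBT0).
#' @param kind `"area"` or `"inner_radius"`.
#' @param Rp protein radius (nm), required for `kind = "inner_radius"` to
#'   convert radius to exchanged area `s = pi (r^2 - Rp^2)`.
#' @param meta optional provenance list (geometry, parameters).
#' @return an object of class `energy_curve` with columns `x`, `s`, `W`.
#' @export
energy_curve <- function(x, W, kind = c("area", "inner_radius"), Rp = NULL,
                         meta = list()) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(W), length(x) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(W))) {
    stop("validation error: energy curve samples must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("validation error: abscissa must be strictly increasing", call. = FALSE)
  }
  s <- if (kind == "area") x else {
    if (is.null(Rp)) stop("Rp required for an inner-radius curve", call. = FALSE)
    pi * (x^2 - Rp^2)
  }
  structure(list(x = x, s = s, W = W, kind = kind, Rp = Rp, meta = meta),
            class = "energy_curve")
}

#' @export
print.energy_curve <- function(x, ...) {
  cat(sprintf("Energy curve (%s abscissa): %d samples, s in [%.3g, %.3g] nm^2, W in [%.4g, %.4g] kBT0\n",
              x$kind, length(x$s), min(x$s), max(x$s), min(x$W), max(x$W)))
  invisible(x)
}

# derivative dW/ds by local quadratic fit over up to `win` nearest samples
.dW_ds <- function(s, W, win = 5L) {
  n <- length(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - win %/% 2L); hi <- min(n, lo + win - 1L)
    lo <- max(1L, hi - win + 1L)
    idx <- lo:hi
    if (length(idx) < 3L) {
      out[i] <- diff(W[range(idx)]) / diff(s[range(idx)])
    } else {
      z <- s[idx] - s[i]
      fit <- stats::lm.fit(cbind(1, z, z^2), W[idx])
      out[i] <- fit$coefficients[2]
    }
  }
  out
}

#' Chemical potential per quasimolecule
#'
#' `mu(s) = a_qm * dW/ds`, from smoothed finite differences (local quadratic
#' fits), normalized so that mu -> 0 as the domain grows without bound.
#'
#' @param curve an [energy_curve()].
#' @param a_qm area per quasimolecule (nm^2).
#' @param check_tail verify the normalization: error if |mu| at the largest
#'   sample exceeds `0.1 * kT * Delta` (the curve then does not reach the
#'   perimeter-dominated regime and a larger size range is required).
#' @param params parameters used for the tail check (kT, Delta).
#' @return numeric vector of mu samples (kBT0).
#' @export
chemical_potential <- function(curve, a_qm, check_tail = TRUE,
                               params = make_params()) {
  stopifnot(inherits(curve, "energy_curve"))
  if (length(curve$s) < 5L) {
    stop("range-too-small error: need at least 5 samples to differentiate",
         call. = FALSE)
  }
  mu <- a_qm * .dW_ds(curve$s, curve$W)
  if (check_tail) {
    thr <- max(0.1 * params$kT * params$Delta, 1e-6)
    if (abs(mu[length(mu)]) > thr) {
      stop(sprintf(
        "range-too-small error: |mu(s_max)| = %.3g exceeds 0.1*kT*Delta = %.3g; extend the size grid",
        abs(mu[length(mu)]), thr), call. = FALSE)
    }
  }
  mu
}

#' Total free energy of the domain under subsaturation
#'
#' `E(s) = W(s) - W(s0) + kT * Delta * (s - s0) / a_qm`, the minimal work to
#' assemble a domain of area s from the no-domain state s0 (first sample).
#' This is the exact integral of `(mu + kT*Delta) dn` with `n = s/a_qm`; no
#' quadrature of mu is involved.
#'
#' @param curve an [energy_curve()].
#' @param params `membrane_params` (kT, Delta, a_qm).
#' @return numeric vector of E samples (kBT0), zero at the first sample.
#' @export
free_energy <- function(curve, params) {
  stopifnot(inherits(curve, "energy_curve"))
  (curve$W - curve$W[1]) +
    params$kT * params$Delta * (curve$s - curve$s[1]) / params$a_qm
}

#' Thermodynamic curves of a wetting domain
#'
#' Bundles an energy curve with its chemical potential and total free
#' energy.
#'
#' @inheritParams free_energy
#' @param check_tail passed to [chemical_potential()].
#' @return an object of class `thermo_curves`: the curve plus `mu`, `E`,
#'   and the parameters used.
#' @export
thermo_curves <- function(curve, params, check_tail = FALSE) {
  mu <- chemical_potential(curve, params$a_qm, check_tail = check_tail,
                           params = params)
  E <- free_energy(curve, params)
  structure(c(unclass(curve), list(mu = mu, E = E, params = params)),
            class = c("thermo_curves", "energy_curve"))
}

#' @export
plot.thermo_curves <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1)); on.exit(par(op))
  plot(x$s, x$E, type = "b", xlab = "ordered-phase area s (nm^2)",
       ylab = "E (kBT0)", pch = 20, ...)
  abline(h = 0, lty = 3)
  plot(x$s, x$mu, type = "b", xlab = "ordered-phase area s (nm^2)",
       ylab = "mu (kBT0)", pch = 20, ...)
  abline(h = -x$params$kT * x$params$Delta, lty = 2, col = "firebrick")
  invisible(x)
}

#' Locate and classify equilibrium domain sizes
#'
#' Finds the interior stationary points of E(s): sign changes of the slope,
#' refined by a local parabolic fit.  The global interior minimum is
#' `stable` when it lies below the no-domain state (first sample) by more
#' than `tie_tol`; other minima are `metastable`, maxima (nucleation
#' barriers) `unstable`.  The first interval is excluded from the search:
#' the first sample is the discrete no-domain state, separated from the
#' domain branch by the minimum admissible domain size, so a sample sitting
#' at that admissibility edge is not an equilibrium (it does not satisfy
#' mu = -kT*Delta).
#'
#' @param tc a `thermo_curves` object (or an `energy_curve` plus `params`).
#' @param params used if `tc` is a bare energy curve.
#' @param tie_tol stability tie-break tolerance (kBT0): a global minimum
#'   within `tie_tol` of the no-domain state is reported as no domain.
#' @return a data.frame with one row per stationary point: `s_eq`, `x_eq`,
#'   `E_eq`, `mu_eq`, `classification` (`stable`/`metastable`/`unstable`);
#'   zero rows mean no interior stationary point.  Attribute `stable` is
#'   TRUE if a stable equilibrium exists.
#' @export
find_equilibria <- function(tc, params = NULL, tie_tol = 1e-3) {
  if (!inherits(tc, "thermo_curves")) {
    tc <- thermo_curves(tc, params)
  }
  E <- tc$E; s <- tc$s; n <- length(E)
  if (n < 5L) stop("range-too-small error: need at least 5 samples", call. = FALSE)
  if (E[n] <= E[n - 1L]) {
    stop("range-too-small error: E still decreasing at the right end; ",
         "extend the size grid past the last stationary point", call. = FALSE)
  }
  # slope of W at an arbitrary point from a local cubic fit (used for the
  # equilibrium-condition residual; more accurate than the mu samples)
  slope_at <- function(sv) {
    idx <- order(abs(s - sv))[seq_len(min(7L, n))]
    z <- s[idx] - sv
    deg <- min(3L, length(idx) - 1L)
    X <- outer(z, 0:deg, `^`)
    stats::lm.fit(X, tc$W[idx])$coefficients[2]
  }
  rows <- NULL
  # local cubic fit of E around a point: value, first and second derivative
  efit <- function(sv) {
    idx <- order(abs(s - sv))[seq_len(min(7L, n))]
    z <- s[idx] - sv
    deg <- min(3L, length(idx) - 1L)
    cf <- stats::lm.fit(outer(z, 0:deg, `^`), E[idx])$coefficients
    cf[is.na(cf)] <- 0
    c(value = cf[1], d1 = cf[2], d2 = if (deg >= 2) 2 * cf[3] else 0)
  }
  # Newton refinement of a stationary point from the grid bracket
  refine <- function(k) {
    sv <- s[k]; h <- max(s[k + 1L] - s[k], s[k] - s[k - 1L])
    for (it in 1:3) {
      ft <- efit(sv)
      if (abs(ft[3]) < 1e-14) break
      step <- -ft[2] / ft[3]
      sv <- sv + max(min(step, h), -h)
    }
    if (sv < s[k - 1L] || sv > s[k + 1L]) sv <- s[k]
    c(sv, unname(efit(sv)[1]))
  }
  for (k in 3:(n - 1L)) {
    is_min <- E[k] < E[k - 1L] && E[k] <= E[k + 1L]
    is_max <- E[k] > E[k - 1L] && E[k] >= E[k + 1L]
    if (!is_min && !is_max) next
    rv <- refine(k)
    mu_eq <- tc$params$a_qm * unname(slope_at(rv[1]))
    rows <- rbind(rows, data.frame(
      s_eq = rv[1],
      x_eq = if (tc$kind == "inner_radius") sqrt(rv[1] / pi + tc$Rp^2) else rv[1],
      E_eq = rv[2], mu_eq = mu_eq,
      classification = if (is_max) "unstable" else "minimum"
    ))
  }
  stable <- FALSE
  if (!is.null(rows) && any(rows$classification == "minimum")) {
    mins <- which(rows$classification == "minimum")
    gm <- mins[which.min(rows$E_eq[mins])]
    rows$classification[mins] <- "metastable"
    if (rows$E_eq[gm] < E[1] - tie_tol) {
      rows$classification[gm] <- "stable"
      stable <- TRUE
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(s_eq = numeric(0), x_eq = numeric(0), E_eq = numeric(0),
                       mu_eq = numeric(0), classification = character(0))
  }
  structure(rows, stable = stable)
}

#' Optimal leaflet partition of a given total ordered area
#'
#' For a fixed total ordered-phase area `s_eq` shared by the two leaflets
#' (`s_eq = pi (Rd^2 - Rp^2) + pi (Ru^2 - Rp^2)`), minimizes the elastic
#' grand potential over the inner radius Rd, with Ru following from the
#' area constraint.  Annuli narrower than `L_min` (but wider than zero) are
#' outside the model's validity and excluded; the boundary minimizer with
#' `Rd = Rp` (or `Ru = Rp`) gives a monolayer domain.
#'
#' @param params `membrane_params`.
#' @param geom `protein_geometry`.
#' @param s_eq total ordered area, nm^2 (>= 0).
#' @param L_min minimum admissible annulus width (nm).
#' @param dL search resolution in the inner width (nm).
#' @param ctrl [solver_control()].
#' @return list with `Rd`, `Ru`, `L_d`, `L_u`, `W`, and `class` in
#'   `none`/`monolayer`/`bilayer`.
#' @export
optimal_partition <- function(params, geom, s_eq, L_min = 2, dL = 0.25,
                              ctrl = solver_control()) {
  stopifnot(s_eq >= 0)
  Rp <- geom$Rp
  if (s_eq <= 1e-9) {
    return(list(Rd = Rp, Ru = Rp, L_d = 0, L_u = 0,
                W = energy_of_configuration(params, geom, Rp, Rp, ctrl),
                class = "none"))
  }
  Rd_of <- function(su) sqrt(pmax(s_eq - su, 0) / pi + Rp^2)
  Ru_full <- sqrt(s_eq / pi + Rp^2)
  # candidate inner radii: monolayer end points plus admissible bilayer splits
  cand_Rd <- c(Rp, Ru_full)
  cand_Ru <- c(Ru_full, Rp)
  Ld_max <- sqrt(s_eq / pi + Rp^2) - Rp
  if (Ld_max > L_min) {
    Lds <- seq(L_min, Ld_max, by = dL)
    Rds <- Rp + Lds
    Rus <- sqrt(pmax(s_eq - pi * (Rds^2 - Rp^2), 0) / pi + Rp^2)
    ok <- (Rus - Rp) >= L_min | (Rus - Rp) < 1e-9
    cand_Rd <- c(cand_Rd, Rds[ok]); cand_Ru <- c(cand_Ru, Rus[ok])
  }
  Ws <- vapply(seq_along(cand_Rd), function(i) {
    energy_of_configuration(params, geom, cand_Rd[i], cand_Ru[i], ctrl)
  }, 1)
  i <- which.min(Ws)
  Rd <- cand_Rd[i]; Ru <- cand_Ru[i]
  cls <- if (Rd - Rp < 1e-9 && Ru - Rp < 1e-9) "none"
  else if (Rd - Rp < 1e-9 || Ru - Rp < 1e-9) "monolayer" else "bilayer"
  list(Rd = Rd, Ru = Ru, L_d = Rd - Rp, L_u = Ru - Rp, W = Ws[i], class = cls)
}
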