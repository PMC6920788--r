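# Parameter scans reproducing the wetting phase portraits: bilayer
# subsaturation (both leaflets subsaturated), monolayer subsaturation
# (outer leaflet saturated, preexisting outer domain), joint width scans
# and the mirror-symmetric film sweep.
#
# Because the minimized elastic grand potential is an exact quadratic in
# the boundary directors (see energy_matrix), a whole (n1, n2) grid costs
# one geometry sweep: scans cache the 3x3 energy matrices per geometry.

# package-level cache of energy grids (keyed by parameter/geometry string)
.memwet_cache <- new.env(parent = emptyenv())

.cache_key <- function(params, Rp, Hp, tag) {
  paste(tag, Rp, Hp,
        paste(unlist(params[c("B", "K", "sigma", "h_r", "h_s")]), collapse = "_"),
        sep = "|")
}

#' Energy-matrix grid over domain geometries
#'
#' Precomputes the quadratic-form matrices `S(Ld, Lu)` such that
#' `W(n1, n2) = 1/2 (1, n1, n2) S (1, n1, n2)'` for every combination of
#' leaflet annulus widths in `Ld_values` x `Lu_values`.
#'
#' @param params `membrane_params`.
#' @param geom `protein_geometry` (its n1, n2 are irrelevant here).
#' @param Ld_values,Lu_values annulus widths (nm); 0 means no annulus.
#' @param ctrl [solver_control()].
#' @param use_cache reuse a previously computed grid for identical inputs.
#' @return an object of class `energy_grid`.
#' @export
energy_grid <- function(params, geom, Ld_values, Lu_values = Ld_values,
                        ctrl = solver_control(), use_cache = TRUE) {
  key <- .cache_key(params, geom$Rp, geom$Hp,
                    paste(c(Ld_values, NA, Lu_values), collapse = ","))
  if (use_cache && !is.null(.memwet_cache[[key]])) return(.memwet_cache[[key]])
  S <- array(NA_real_, c(length(Ld_values), length(Lu_values), 3, 3))
  for (i in seq_along(Ld_values)) {
    for (j in seq_along(Lu_values)) {
      conf <- domain_configuration(geom$Rp + Ld_values[i],
                                   geom$Rp + Lu_values[j], geom)
      S[i, j, , ] <- energy_matrix(params, geom, conf, ctrl)
    }
  }
  out <- structure(list(Ld = Ld_values, Lu = Lu_values, S = S,
                        Rp = geom$Rp, Hp = geom$Hp, params = params),
                   class = "energy_grid")
  if (use_cache) .memwet_cache[[key]] <- out
  out
}

# W over the whole grid for given boundary directors
.grid_W <- function(grid, n1, n2) {
  y <- c(1, n1, n2)
  apply(grid$S, c(1, 2), function(S) sum(y * (matrix(S, 3, 3) %*% y)) / 2)
}

# default admissible width ladder: no annulus, then L_min..L_max
.width_ladder <- function(L_min, L_max, dL) c(0, seq(L_min, L_max, by = dL))

.director_grid <- function(grid_step) {
  stopifnot(grid_step %in% c(0.05, 0.1, 0.2))
  round(seq(-0.7, 0.7, by = grid_step), 10)
}

#' Bilayer-subsaturation wetting portrait
#'
#' Both leaflets are subsaturated; the free energy `E(s)` of a growing
#' bilayer-symmetric domain (equal annulus widths in the two leaflets) is
#' scanned for each boundary-director combination, equilibria are located,
#' and for stable cells the leaflet partition is then optimized at the
#' equilibrium area `s_eq` and the cell classified as a monolayer or
#' bilayer domain.
#'
#' @param params `membrane_params`.
#' @param Rp protein radius (nm); `Hp = 2 h_r` (no mismatch with the
#'   ordered phase).
#' @param grid_step director grid step (0.05, 0.1 or 0.2).
#' @param L_min minimum admissible annulus width (nm).
#' @param L_max largest annulus width scanned (nm).
#' @param dL width resolution (nm).
#' @param ctrl [solver_control()].
#' @return a `phase_portrait` object: data.frame of cells with columns
#'   `n1`, `n2`, `class` (`none`/`monolayer`/`bilayer`/`failed`), `s_eq`,
#'   `Rd`, `Ru`, `L_d`, `L_u`, `E_eq`, `mu_res` (residual of the
#'   equilibrium condition mu + kT Delta).
#' @export
bilayer_wetting_portrait <- function(params, Rp = 1.6, grid_step = 0.1,
                                     L_min = 2, L_max = 14, dL = 0.5,
                                     ctrl = solver_control()) {
  geom0 <- protein_geometry(Rp, 2 * params$h_r, 0, 0)
  Ls <- .width_ladder(L_min, L_max, dL)
  dia <- energy_grid(params, geom0, Ls, Ls, ctrl)
  idx <- cbind(seq_along(Ls), seq_along(Ls))
  ns <- .director_grid(grid_step)
  cells <- expand.grid(n1 = ns, n2 = ns, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  s_of <- 2 * pi * ((Rp + Ls)^2 - Rp^2)
  for (cix in seq_len(nrow(cells))) {
    n1 <- cells$n1[cix]; n2 <- cells$n2[cix]
    res[[cix]] <- tryCatch({
      y <- c(1, n1, n2)
      W <- vapply(seq_along(Ls), function(k) {
        sum(y * (matrix(dia$S[k, k, , ], 3, 3) %*% y)) / 2
      }, 1)
      tc <- thermo_curves(energy_curve(s_of, W, "area"), params)
      eq <- find_equilibria(tc)
      if (!attr(eq, "stable")) {
        data.frame(n1 = n1, n2 = n2, class = "none", s_eq = NA, Rd = NA,
                   Ru = NA, L_d = NA, L_u = NA, E_eq = NA, mu_res = NA)
      } else {
        st <- eq[eq$classification == "stable", ]
        part <- optimal_partition(params, protein_geometry(Rp, geom0$Hp, n1, n2),
                                  st$s_eq, L_min = L_min, ctrl = ctrl)
        data.frame(n1 = n1, n2 = n2, class = part$class, s_eq = st$s_eq,
                   Rd = part$Rd, Ru = part$Ru, L_d = part$L_d, L_u = part$L_u,
                   E_eq = st$E_eq,
                   mu_res = st$mu_eq + params$kT * params$Delta)
      }
    }, error = function(e) {
      warning("cell (", n1, ", ", n2, ") failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(n1 = n1, n2 = n2, class = "failed", s_eq = NA, Rd = NA,
                 Ru = NA, L_d = NA, L_u = NA, E_eq = NA, mu_res = NA)
    })
  }
  out <- do.call(rbind, res)
  structure(out, class = c("phase_portrait", "data.frame"),
            mode = "bilayer", Rp = Rp, grid_step = grid_step,
            L_min = L_min, L_max = L_max, dL = dL)
}

#' Monolayer-subsaturation wetting portrait
#'
#' The outer leaflet is saturated and carries a preexisting ordered domain
#' of fixed radius `Ru = Rp + L_u_fixed`; only the inner leaflet is
#' subsaturated.  For each director combination the grand potential `W(r)`
#' over the inner-domain radius is converted to `E(r)` with the
#' subsaturation penalty applied to the inner-leaflet ordered area only,
#' and cells with a stable interior minimum are classified as
#' `inner-domain`.
#'
#' @inheritParams bilayer_wetting_portrait
#' @param L_u_fixed fixed outer annulus width (nm).
#' @return a `phase_portrait` object (classes `none`/`inner-domain`).
#' @export
monolayer_wetting_portrait <- function(params, Rp = 1.6, L_u_fixed = 7,
                                       grid_step = 0.1, L_min = 2,
                                       L_max = 14, dL = 0.25,
                                       ctrl = solver_control()) {
  stopifnot(L_u_fixed > 0)
  geom0 <- protein_geometry(Rp, 2 * params$h_r, 0, 0)
  Lds <- .width_ladder(L_min, L_max, dL)
  line <- energy_grid(params, geom0, Lds, L_u_fixed, ctrl)
  ns <- .director_grid(grid_step)
  cells <- expand.grid(n1 = ns, n2 = ns, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  r_of <- Rp + Lds
  for (cix in seq_len(nrow(cells))) {
    n1 <- cells$n1[cix]; n2 <- cells$n2[cix]
    res[[cix]] <- tryCatch({
      y <- c(1, n1, n2)
      W <- vapply(seq_along(Lds), function(k) {
        sum(y * (matrix(line$S[k, 1, , ], 3, 3) %*% y)) / 2
      }, 1)
      tc <- thermo_curves(energy_curve(r_of, W, "inner_radius", Rp = Rp),
                          params)
      eq <- find_equilibria(tc)
      if (!attr(eq, "stable")) {
        data.frame(n1 = n1, n2 = n2, class = "none", s_eq = NA, Rd = NA,
                   Ru = Rp + L_u_fixed, L_d = NA, L_u = L_u_fixed,
                   E_eq = NA, mu_res = NA)
      } else {
        st <- eq[eq$classification == "stable", ]
        data.frame(n1 = n1, n2 = n2, class = "inner-domain", s_eq = st$s_eq,
                   Rd = st$x_eq, Ru = Rp + L_u_fixed, L_d = st$x_eq - Rp,
                   L_u = L_u_fixed, E_eq = st$E_eq,
                   mu_res = st$mu_eq + params$kT * params$Delta)
      }
    }, error = function(e) {
      warning("cell (", n1, ", ", n2, ") failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(n1 = n1, n2 = n2, class = "failed", s_eq = NA, Rd = NA,
                 Ru = Rp + L_u_fixed, L_d = NA, L_u = L_u_fixed, E_eq = NA,
                 mu_res = NA)
    })
  }
  out <- do.call(rbind, res)
  structure(out, class = c("phase_portrait", "data.frame"),
            mode = "monolayer", Rp = Rp, grid_step = grid_step,
            L_min = L_min, L_max = L_max, dL = dL, L_u_fixed = L_u_fixed)
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("Wetting phase portrait (%s subsaturation), Rp = %g nm, grid step %g\n",
              attr(x, "mode"), attr(x, "Rp"), attr(x, "grid_step")))
  print(table(x$class))
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  ns1 <- sort(unique(x$n1)); ns2 <- sort(unique(x$n2))
  lv <- c("none", "monolayer", "bilayer", "inner-domain", "failed")
  z <- matrix(match(x$class, lv), length(ns1), length(ns2))
  cols <- c("grey92", "orchid", "seagreen3", "orchid4", "red")
  image(ns1, ns2, z, col = cols[sort(unique(as.vector(z)))],
        xlab = "n1 (outer boundary director)",
        ylab = "n2 (inner boundary director)", ...)
  invisible(x)
}

#' Joint stable-domain width scan
#'
#' Emulates the exploration of the full geometry space in the
#' monolayer-subsaturation setting: for each boundary-director combination,
#' searches the two-dimensional energy landscape `E(L_d, L_u)` (penalty on
#' the inner-leaflet area only; the saturated outer leaflet equilibrates
#' elastically) for interior local minima with both annuli present, i.e.
#' genuinely bilayer-spanning stable domains, and records their widths.
#'
#' @inheritParams monolayer_wetting_portrait
#' @param L_u_ref reference outer width of the no-inner-domain baseline
#'   state (nm).
#' @return data.frame per cell: `n1`, `n2`, `stable`, `L_d`, `L_u`, `E_rel`
#'   (depth below the baseline), with attribute `widths` (means).
#' @export
stable_width_scan <- function(params, Rp = 1.6, grid_step = 0.1, L_min = 2,
                              L_max = 12, dL = 0.5, L_u_ref = 7,
                              ctrl = solver_control()) {
  geom0 <- protein_geometry(Rp, 2 * params$h_r, 0, 0)
  Ls <- .width_ladder(L_min, L_max, dL)
  grid <- energy_grid(params, geom0, Ls, Ls, ctrl)
  ns <- .director_grid(grid_step)
  pen <- params$kT * params$Delta * pi * ((Rp + Ls)^2 - Rp^2) / params$a_qm
  iref <- which.min(abs(Ls - L_u_ref))
  ni <- length(Ls)
  out <- NULL
  for (n1 in ns) for (n2 in ns) {
    W <- .grid_W(grid, n1, n2)
    E <- W + matrix(pen, ni, ni)
    best <- NULL
    for (i in 3:(ni - 1L)) for (j in 3:(ni - 1L)) {
      if (E[i, j] <= E[i + 1L, j] && E[i, j] < E[i - 1L, j] &&
          E[i, j] <= E[i, j + 1L] && E[i, j] < E[i, j - 1L]) {
        if (is.null(best) || E[i, j] < best$E) {
          best <- list(E = E[i, j], i = i, j = j)
        }
      }
    }
    base <- E[1L, iref]
    stable <- !is.null(best) && best$E < base - 1e-3
    ref1 <- function(k, Ek) {  # parabolic width refinement along one axis
      d2 <- Ek[3] - 2 * Ek[2] + Ek[1]
      if (d2 <= 0) return(Ls[k])
      Ls[k] - dL * (Ek[3] - Ek[1]) / (2 * d2)
    }
    out <- rbind(out, data.frame(
      n1 = n1, n2 = n2, stable = stable,
      L_d = if (stable) ref1(best$i, E[(best$i - 1):(best$i + 1), best$j]) else NA,
      L_u = if (stable) ref1(best$j, E[best$i, (best$j - 1):(best$j + 1)]) else NA,
      E_rel = if (stable) best$E - base else NA
    ))
  }
  attr(out, "Rp") <- Rp
  attr(out, "widths") <- c(L_d = mean(out$L_d, na.rm = TRUE),
                           L_u = mean(out$L_u, na.rm = TRUE))
  out
}

#' Width statistics of stable domains
#'
#' Summarizes the per-configuration leaflet widths of stable domains from a
#' [stable_width_scan()] (or any data.frame with logical `stable` and
#' numeric `L_d`, `L_u`), and flags a spread larger than 30 percent of the
#' mean, which would contradict the expectation that the widths are nearly
#' parameter-independent.
#'
#' @param scan the scan result.
#' @return list with `n`, `L_u` / `L_d` (mean, sd, spread fraction) and
#'   `wide_spread` flag.
#' @export
measure_stable_widths <- function(scan) {
  st <- scan[which(scan$stable), , drop = FALSE]
  if (nrow(st) == 0L) stop("empty sample: no stable configurations", call. = FALSE)
  f <- function(v) {
    m <- mean(v); sdv <- if (length(v) > 1L) stats::sd(v) else 0
    c(mean = m, sd = sdv, spread = if (m > 0) sdv / m else 0)
  }
  lu <- f(st$L_u); ld <- f(st$L_d)
  list(n = nrow(st), L_u = lu, L_d = ld,
       wide_spread = lu[["spread"]] > 0.3 || ld[["spread"]] > 0.3)
}

#' Mirror-symmetric ordered-film sweep
#'
#' Legacy check: a mirror-symmetric membrane (equal annulus widths, zero
#' boundary directors, protein centred) wetted under bilayer subsaturation.
#' For each protein radius the equilibrium film width is the interior
#' stationary minimum of E(L) below the no-film state; 0 if none.
#'
#' @param params `membrane_params`.
#' @param Rp_values protein radii to sweep (nm).
#' @param Delta subsaturation override (defaults to `params$Delta`).
#' @param L_min,L_max,dL admissible width ladder (nm).
#' @param ctrl [solver_control()].
#' @return data.frame with `Rp` and `width` (nm).
#' @export
symmetric_film_scan <- function(params, Rp_values, Delta = NULL,
                                L_min = 2, L_max = 12, dL = 0.25,
                                ctrl = solver_control()) {
  if (!is.null(Delta)) {
    params$Delta <- Delta
    validate_params(params)
  }
  widths <- vapply(Rp_values, function(Rp) {
    geom0 <- protein_geometry(Rp, 2 * params$h_r, 0, 0)
    Ls <- .width_ladder(L_min, L_max, dL)
    W <- vapply(Ls, function(L) {
      energy_of_configuration(params, geom0, Rp + L, Rp + L, ctrl)
    }, 1)
    tc <- thermo_curves(energy_curve(2 * pi * ((Rp + Ls)^2 - Rp^2), W, "area"),
                        params)
    eq <- find_equilibria(tc)
    if (!attr(eq, "stable")) return(0)
    s_eq <- eq$s_eq[eq$classification == "stable"]
    sqrt(s_eq / (2 * pi) + Rp^2) - Rp
  }, 1)
  out <- data.frame(Rp = Rp_values, width = widths)
  if (any(diff(out$width[order(out$Rp)]) < -0.3)) {
    warning("film width not non-decreasing in Rp beyond scan resolution",
            call. = FALSE)
  }
  out
}

#' EGFR conformation wetting report
#'
#' Runs the bilayer- and monolayer-subsaturation portraits for the closed
#' (Rp = 0.9 nm) and open (Rp = 1.6 nm) conformations, overlays the
#' conformation-characteristic director regions (closed: n1 < 0, n2 ~ 0;
#' open: n1 > 0, n2 < 0), and ranks the transmembrane-domain shape classes
#' (barrel, cone, inverted cone, hourglass) by their stable-cell counts.
#'
#' @param params `membrane_params`.
#' @param grid_step director grid step.
#' @param ... passed to the portrait functions.
#' @return an object of class `egfr_report`.
#' @export
egfr_report <- function(params = make_params(), grid_step = 0.1, ...) {
  radii <- c(closed = 0.9, open = 1.6)
  bil <- lapply(radii, function(Rp) {
    bilayer_wetting_portrait(params, Rp, grid_step = grid_step, ...)
  })
  mono <- lapply(radii, function(Rp) {
    monolayer_wetting_portrait(params, Rp, grid_step = grid_step, ...)
  })
  in_closed <- function(df) df$n1 < 0 & abs(df$n2) <= 0.1
  in_open <- function(df) df$n1 > 0 & df$n2 < 0
  stable <- function(df) !df$class %in% c("none", "failed")
  quadrant_counts <- function(df) {
    st <- stable(df)
    c(barrel = sum(st & df$n1 > 0 & df$n2 > 0),
      cone = sum(st & df$n1 > 0 & df$n2 < 0),
      inverted_cone = sum(st & df$n1 < 0 & df$n2 > 0),
      hourglass = sum(st & df$n1 < 0 & df$n2 < 0))
  }
  qc <- quadrant_counts(mono$open)
  eff <- names(sort(qc, decreasing = TRUE))
  structure(list(
    portraits = list(bilayer = bil, monolayer = mono),
    closed_region_stable = list(
      bilayer = sum(stable(bil$closed) & in_closed(bil$closed)),
      monolayer = sum(stable(mono$closed) & in_closed(mono$closed))),
    open_region_stable = list(
      bilayer = sum(stable(bil$open) & in_open(bil$open)),
      monolayer = sum(stable(mono$open) & in_open(mono$open))),
    quadrant_counts = qc,
    efficiency_order = eff
  ), class = "egfr_report")
}

#' @export
print.egfr_report <- function(x, ...) {
  cat("EGFR TMD wetting report\n")
  cat("  stable cells in closed-characteristic region (n1<0, |n2|<=0.1):\n")
  cat(sprintf("    bilayer mode: %d, monolayer mode: %d\n",
              x$closed_region_stable$bilayer, x$closed_region_stable$monolayer))
  cat("  stable cells in open-characteristic region (n1>0, n2<0):\n")
  cat(sprintf("    bilayer mode: %d, monolayer mode: %d\n",
              x$open_region_stable$bilayer, x$open_region_stable$monolayer))
  cat("  stable-cell counts by TMD shape (monolayer mode, open Rp):\n")
  print(x$quadrant_counts)
  cat("  wetting efficiency order:", paste(x$efficiency_order, collapse = " > "),
      "\n")
  invisible(x)
}
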