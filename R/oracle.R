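# Brute-force variational oracle: second-order finite-difference
# transcription of the elastic functional, minimized exactly as a
# constrained quadratic form.  Independent of the Galerkin route in
# elastic_solver: nodal values only (no derivative DOFs), one-sided
# difference stencils at region edges, trapezoid quadrature.  Same field
# reduction (H_a, H_b eliminated via incompressibility), same truncation
# and gauge, so the two routes minimize the identical continuum functional.

# finite-difference operators on a uniform grid of n nodes, step h:
# value (identity), first and second derivative, all second-order accurate
# including one-sided stencils at the two ends.
.fd_ops <- function(n, h) {
  stopifnot(n >= 5)
  I <- Matrix::Diagonal(n)
  i1 <- c(1, 1, 1, rep(2:(n - 1), each = 2), n, n, n)
  j1 <- c(1, 2, 3, as.vector(rbind(1:(n - 2), 3:n)), n - 2, n - 1, n)
  x1 <- c(-3, 4, -1, rep(c(-1, 1), n - 2), 1, -4, 3) / (2 * h)
  D1 <- Matrix::sparseMatrix(i = i1, j = j1, x = x1, dims = c(n, n))
  # staggered (node -> cell midpoint) operators: average and difference
  iA <- rep(seq_len(n - 1), 2)
  Av <- Matrix::sparseMatrix(i = iA, j = c(1:(n - 1), 2:n),
                             x = rep(0.5, 2 * (n - 1)), dims = c(n - 1, n))
  Df <- Matrix::sparseMatrix(i = iA, j = c(1:(n - 1), 2:n),
                             x = rep(c(-1, 1) / h, each = n - 1),
                             dims = c(n - 1, n))
  list(I = I, D1 = D1, Av = Av, Df = Df)
}

#' Finite-difference transcription of the elastic functional
#'
#' Discretizes the tilt + splay + tension functional on uniform per-region
#' radial grids, with the neutral surfaces eliminated through the
#' incompressibility condition, as a quadratic form over the nodal values
#' of (n_a, n_b, M) plus linear constraint rows encoding the wall, interface
#' and far-field conditions.  Used as a brute-force correctness oracle for
#' the Galerkin solver.
#'
#' @inheritParams build_regions
#' @param grid_step target node spacing (nm); must resolve the tilt decay
#'   length sqrt(B/K) with at least 10 nodes.
#' @param far truncation margin past the outermost region boundary (nm),
#'   identical in meaning to [solver_control()]'s.
#' @return an object of class `discretized_functional` with elements `Q`
#'   (quadratic form), `C` and `dmat` (constraints; RHS basis for
#'   `(1, n1, n2)`), `r` (node radii), `region` (region id per node) and the
#'   problem definition.
#' @export
discretize <- function(params, geom, conf, grid_step = 0.025, far = 80) {
  lam <- sqrt(params$B / params$K)
  if (grid_step > lam / 10) {
    stop("grid too coarse: grid_step must be <= sqrt(B/K)/10 = ",
         signif(lam / 10, 3), " nm to resolve the tilt decay length",
         call. = FALSE)
  }
  regions <- build_regions(params, geom, conf)
  nreg <- nrow(regions)
  regions$r_out[nreg] <- regions$r_in[nreg] + far

  nodes <- list(); ops <- list()
  for (k in seq_len(nreg)) {
    w <- regions$r_out[k] - regions$r_in[k]
    n <- max(5L, ceiling(w / grid_step) + 1L)
    h <- w / (n - 1)
    nodes[[k]] <- seq(regions$r_in[k], regions$r_out[k], length.out = n)
    ops[[k]] <- .fd_ops(n, h)
  }
  nn <- vapply(nodes, length, 1L)
  off <- cumsum(c(0L, nn[-nreg]))
  nnode <- sum(nn)
  r_all <- unlist(nodes)
  reg_all <- rep(seq_len(nreg), nn)

  # energy on the staggered grid: all quantities at cell midpoints from
  # compact two-point stencils (second-order, no wide one-sided formulas)
  Dg <- function(v) Matrix::Diagonal(x = v)
  per_region <- function(k) {
    o <- ops[[k]]; r <- nodes[[k]]
    m <- (r[-1] + r[-length(r)]) / 2
    Danode <- o$D1 + Dg(1 / r)
    list(Div = o$Df + Dg(1 / m) %*% o$Av,     # div n at midpoints
         Dp = o$Df %*% Danode,                # (div n)' at midpoints
         Av = o$Av, DfM = o$Df, m = m,
         ha = regions$h0_upper[k], hb = regions$h0_lower[k])
  }
  pr <- lapply(seq_len(nreg), per_region)
  blk <- function(which) Matrix::bdiag(lapply(pr, `[[`, which))
  m_all <- unlist(lapply(pr, `[[`, "m"))
  nmid <- length(m_all)
  ha_mid <- rep(vapply(pr, `[[`, 1, "ha"), nn - 1L)
  hb_mid <- rep(vapply(pr, `[[`, 1, "hb"), nn - 1L)
  wt_all <- unlist(lapply(seq_len(nreg),
                          function(k) rep(diff(nodes[[k]])[1], nn[k] - 1L))) *
    2 * pi * m_all

  Zn <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(nmid, nnode))
  pad <- function(op, slot) {
    parts <- list(Zn, Zn, Zn); parts[[slot]] <- op
    do.call(cbind, parts)
  }
  Div_a <- pad(blk("Div"), 1)
  Div_b <- pad(blk("Div"), 2)
  S_a <- pad(blk("DfM"), 3) - Dg(ha_mid^2 / 2) %*% pad(blk("Dp"), 1)
  S_b <- pad(blk("DfM"), 3) + Dg(hb_mid^2 / 2) %*% pad(blk("Dp"), 2)
  T_a <- pad(blk("Av"), 1) - S_a
  T_b <- pad(blk("Av"), 2) + S_b

  quad <- function(op, coef) Matrix::t(op) %*% Dg(coef * wt_all) %*% op
  Q <- quad(Div_a, params$B) + quad(Div_b, params$B) +
    quad(T_a, params$K) + quad(T_b, params$K) +
    quad(S_a, params$sigma) + quad(S_b, params$sigma)
  Q <- Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)

  # ---- constraints (same physical set as the Galerkin solver) -----------
  adof <- function(n) n; bdof <- function(n) nnode + n
  Mdof <- function(n) 2L * nnode + n
  rows_i <- integer(0); rows_j <- integer(0); rows_x <- numeric(0)
  dmat <- NULL
  add_row <- function(cols, vals, d) {
    k <- if (is.null(dmat)) 1L else nrow(dmat) + 1L
    rows_i <<- c(rows_i, rep.int(k, length(cols)))
    rows_j <<- c(rows_j, cols); rows_x <<- c(rows_x, vals)
    dmat <<- rbind(dmat, d)
  }
  D1t <- methods::as(Matrix::bdiag(lapply(ops, `[[`, "D1")), "TsparseMatrix")
  d1row <- function(node) {        # global node-derivative row (cols, vals)
    sel <- which(D1t@i == node - 1L)
    list(cols = D1t@j[sel] + 1L, vals = D1t@x[sel])
  }
  n_wall <- off[1] + 1L
  Rp <- geom$Rp
  ha1 <- regions$h0_upper[1]; hb1 <- regions$h0_lower[1]
  add_row(adof(n_wall), 1, c(0, 1, 0))
  add_row(bdof(n_wall), 1, c(0, 0, 1))
  rw <- d1row(n_wall)
  add_row(c(adof(rw$cols), adof(n_wall), bdof(rw$cols), bdof(n_wall)),
          c(-ha1^2 / 2 * rw$vals, -ha1^2 / 2 / Rp,
            -hb1^2 / 2 * rw$vals, -hb1^2 / 2 / Rp),
          c(geom$Hp - ha1 - hb1, 0, 0))
  if (nreg > 1) {
    for (k in seq_len(nreg - 1L)) {
      nL <- off[k] + nn[k]; nR <- off[k + 1L] + 1L
      rs <- regions$r_out[k]
      add_row(c(adof(nL), adof(nR)), c(1, -1), c(0, 0, 0))
      add_row(c(bdof(nL), bdof(nR)), c(1, -1), c(0, 0, 0))
      haL <- regions$h0_upper[k]; haR <- regions$h0_upper[k + 1L]
      hbL <- regions$h0_lower[k]; hbR <- regions$h0_lower[k + 1L]
      rL <- d1row(nL); rR <- d1row(nR)
      add_row(c(Mdof(nL), Mdof(nR),
                adof(rL$cols), adof(nL), adof(rR$cols), adof(nR)),
              c(1, -1,
                -haL^2 / 2 * rL$vals, -haL^2 / 2 / rs,
                haR^2 / 2 * rR$vals, haR^2 / 2 / rs),
              c(haR - haL, 0, 0))
      add_row(c(Mdof(nL), Mdof(nR),
                bdof(rL$cols), bdof(nL), bdof(rR$cols), bdof(nR)),
              c(1, -1,
                hbL^2 / 2 * rL$vals, hbL^2 / 2 / rs,
                -hbR^2 / 2 * rR$vals, -hbR^2 / 2 / rs),
              c(hbL - hbR, 0, 0))
    }
  }
  add_row(adof(nnode), 1, c(0, 0, 0))
  add_row(bdof(nnode), 1, c(0, 0, 0))
  add_row(Mdof(nnode), 1, c(0, 0, 0))
  C <- Matrix::sparseMatrix(i = rows_i, j = rows_j, x = rows_x,
                            dims = c(nrow(dmat), 3L * nnode))

  structure(list(Q = Q, C = C, dmat = dmat, r = r_all, region = reg_all,
                 nnode = nnode, grid_step = grid_step,
                 params = params, geom = geom, conf = conf),
            class = "discretized_functional")
}

#' Exact minimization of a discretized elastic functional
#'
#' Single constrained linear solve: no iteration, deterministic.
#'
#' @param f a `discretized_functional` from [discretize()].
#' @return list with `W` (minimized energy, kBT0) and `profile`, a
#'   data.frame of the nodal fields (`r`, `n_a`, `n_b`, `M`, `region`).
#' @export
minimize_direct <- function(f) {
  d <- f$dmat %*% c(1, f$geom$n1, f$geom$n2)
  x <- .min_quadratic(f$Q, f$C, d)[, 1]
  W <- as.numeric(x %*% (f$Q %*% x)) / 2
  n <- f$nnode
  profile <- data.frame(r = f$r, n_a = x[seq_len(n)],
                        n_b = x[n + seq_len(n)], M = x[2L * n + seq_len(n)],
                        region = f$region)
  list(W = W, profile = profile)
}

#' Oracle energy of a configuration
#'
#' Convenience wrapper: [discretize()] then [minimize_direct()].
#'
#' @inheritParams discretize
#' @return minimized energy W (kBT0).
#' @export
oracle_energy <- function(params, geom, conf, grid_step = 0.025, far = 80) {
  minimize_direct(discretize(params, geom, conf, grid_step, far))$W
}

#' Straight-wall (planar) limit of the deformation energy
#'
#' Solves the translationally invariant analogue of the wetting problem: a
#' straight rigid wall at x = 0 imposing the same boundary director `n0` on
#' both leaflets, with no thickness mismatch anywhere.  Used to check the
#' cylindrical solver in the large-radius limit, where the energy per unit
#' length of wall must approach this value.
#'
#' @param n0 boundary director projection, |n0| <= 0.7.
#' @param params `membrane_params`.
#' @param grid_step node spacing (nm).
#' @param L domain length (nm).
#' @return energy per unit length of wall (kBT0/nm).
#' @export
planar_limit_energy <- function(n0, params, grid_step = 0.01, L = 60) {
  if (abs(n0) > 0.7 + 1e-12) {
    stop("validation error: |n0| must be <= 0.7", call. = FALSE)
  }
  hs <- params$h_s
  n <- ceiling(L / grid_step) + 1L
  h <- L / (n - 1)
  ops <- .fd_ops(n, h)
  D1 <- ops$D1; Av <- ops$Av; Df <- ops$Df
  Zn <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n - 1L, n))
  pad <- function(op, slot) {
    parts <- list(Zn, Zn, Zn); parts[[slot]] <- op
    do.call(cbind, parts)
  }
  al <- hs^2 / 2
  Dp <- Df %*% D1                       # second derivative at midpoints
  S_a <- pad(Df, 3) - al * pad(Dp, 1)
  S_b <- pad(Df, 3) + al * pad(Dp, 2)
  T_a <- pad(Av, 1) - S_a
  T_b <- pad(Av, 2) + S_b
  Da <- pad(Df, 1); Db <- pad(Df, 2)
  wt <- rep(h, n - 1L)
  Dg <- function(v) Matrix::Diagonal(x = v)
  quad <- function(op, coef) Matrix::t(op) %*% Dg(coef * wt) %*% op
  Q <- quad(Da, params$B) + quad(Db, params$B) +
    quad(T_a, params$K) + quad(T_b, params$K) +
    quad(S_a, params$sigma) + quad(S_b, params$sigma)
  Q <- Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)
  D1t <- methods::as(D1, "TsparseMatrix")
  sel <- which(D1t@i == 0L)
  cols <- D1t@j[sel] + 1L; vals <- D1t@x[sel]
  C <- Matrix::sparseMatrix(
    i = c(1L, 2L, rep(3L, 2L * length(cols)), 4L, 5L, 6L),
    j = c(1L, n + 1L, cols, n + cols, n, 2L * n, 3L * n),
    x = c(1, 1, -al * vals, -al * vals, 1, 1, 1),
    dims = c(6L, 3L * n))
  d <- c(n0, n0, 0, 0, 0, 0)
  x <- .min_quadratic(Q, C, d)[, 1]
  as.numeric(x %*% (Q %*% x)) / 2
}
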