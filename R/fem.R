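# Elastic boundary-value problem: Hermite-cubic Ritz/Galerkin solver.
#
# Fields per radius r (all measured from the flat reference state):
#   a(r), b(r)  director radial projections of the outer/inner leaflet
#   M(r)        intermonolayer surface height
# Derived via local volumetric incompressibility (h = h0 - h0^2/2 div n):
#   H_a = M + h0a - (h0a^2/2) div a        (outer neutral surface)
#   H_b = M - h0b + (h0b^2/2) div b        (inner neutral surface)
#   t_a = a - H_a',  t_b = b + H_b'        (tilt projections)
# Energy density per leaflet, cylindrical measure 2*pi*r dr:
#   B/2 (div n)^2 + K/2 t^2 + sigma/2 (H')^2,   div n = n' + n/r.
# The energy is a positive-semidefinite quadratic form in the nodal degrees
# of freedom; boundary, interface-continuity and far-field conditions are
# linear constraints, so the minimizer solves one sparse KKT system.  At the
# discrete level this is exactly the Euler-Lagrange system of the functional
# in weak form; free director values at the domain edges and the protein's
# vertical offset are unconstrained DOFs, i.e. fixed by energy minimization.

#' Solver control settings
#'
#' @param h_min smallest element size, used next to region boundaries (nm).
#' @param h_max largest element size in smooth zones (nm).
#' @param grow geometric growth factor of element sizes away from boundaries.
#' @param far truncation margin past the outermost region boundary (nm);
#'   all deformations are clamped to zero there. The slowest decay length of
#'   the system at the reference parameters is sqrt(B/sigma) ~ 32 nm
#'   (bilayer bending against tension), so `far` must be a few times that.
#' @param ngauss Gauss-Legendre points per element.
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(h_min = 0.1, h_max = 2.0, grow = 1.35,
                           far = 80, ngauss = 5) {
  stopifnot(h_min > 0, h_max >= h_min, grow > 1, far > 10, ngauss >= 3)
  structure(list(h_min = h_min, h_max = h_max, grow = grow, far = far,
                 ngauss = ngauss), class = "solver_control")
}

# graded offsets 0 < d_1 < ... <= cap from one end
.grade_offsets <- function(cap, h0, grow, hmax) {
  out <- numeric(0); off <- 0; h <- h0
  while (off < cap - 1e-12) {
    off <- min(off + h, cap)
    out <- c(out, off)
    h <- min(h * grow, hmax)
  }
  out
}

# node positions for one region; refine = "both" or "left"
.mesh_region <- function(rin, rout, ctrl, refine = "both") {
  w <- rout - rin
  if (w <= 2 * ctrl$h_min) {
    return(seq(rin, rout, length.out = max(3L, ceiling(w / (ctrl$h_min / 2)) + 1L)))
  }
  if (refine == "left") {
    nodes <- c(rin, rin + .grade_offsets(w, ctrl$h_min, ctrl$grow, ctrl$h_max))
  } else {
    lo <- .grade_offsets(w / 2, ctrl$h_min, ctrl$grow, ctrl$h_max)
    nodes <- sort(unique(c(rin, rin + lo, rout - lo, rout)))
  }
  # drop nodes that ended up closer than half the local minimum size
  keep <- c(TRUE, diff(nodes) > ctrl$h_min * 0.45)
  keep[length(keep)] <- TRUE
  nodes <- nodes[keep]
  if (nodes[length(nodes)] != rout) nodes <- c(nodes, rout)
  nodes
}

.gauss01 <- function(n) {
  g <- pracma::gaussLegendre(n, 0, 1)
  list(x = g$x, w = g$w)
}

# Hermite cubic shape values/derivatives on [0,1] at points xi.
# Returns list of 3 matrices (value, d/dxi, d2/dxi2), each length(xi) x 4,
# DOF order (f1, f1', f2, f2') with the derivative DOFs in d/dr units
# (scaling by element length is applied by the caller).
.hermite_basis <- function(xi) {
  v <- cbind(2 * xi^3 - 3 * xi^2 + 1,
             xi^3 - 2 * xi^2 + xi,
             -2 * xi^3 + 3 * xi^2,
             xi^3 - xi^2)
  d1 <- cbind(6 * xi^2 - 6 * xi,
              3 * xi^2 - 4 * xi + 1,
              -6 * xi^2 + 6 * xi,
              3 * xi^2 - 2 * xi)
  d2 <- cbind(12 * xi - 6,
              6 * xi - 4,
              -12 * xi + 6,
              6 * xi - 2)
  list(v = v, d1 = d1, d2 = d2)
}

# Assemble the discretized elastic problem.
# Returns an environment holding the quadratic form Q, the constraint matrix
# C with RHS basis (const, n1, n2), quantity operators for energy breakdown
# and profile evaluation, and mesh bookkeeping.
.assemble_fem <- function(params, geom, conf, ctrl = solver_control()) {
  regions <- build_regions(params, geom, conf)
  nreg <- nrow(regions)
  r_last <- regions$r_in[nreg]
  r_end <- r_last + ctrl$far
  regions$r_out[nreg] <- r_end

  node_list <- vector("list", nreg)
  for (k in seq_len(nreg)) {
    node_list[[k]] <- .mesh_region(regions$r_in[k], regions$r_out[k], ctrl,
                                   refine = if (k == nreg) "left" else "both")
  }
  nn <- vapply(node_list, length, 1L)
  node_off <- cumsum(c(0L, nn[-nreg]))          # global node index offset
  nnode <- sum(nn)
  ndof <- 6L * nnode                            # (a, a', b, b', M, M') per node

  # element table
  el_n1 <- integer(0); el_r1 <- numeric(0); el_h <- numeric(0)
  el_reg <- integer(0)
  for (k in seq_len(nreg)) {
    nd <- node_list[[k]]
    ne <- length(nd) - 1L
    el_n1 <- c(el_n1, node_off[k] + seq_len(ne))
    el_r1 <- c(el_r1, nd[-length(nd)])
    el_h <- c(el_h, diff(nd))
    el_reg <- c(el_reg, rep.int(k, ne))
  }
  nel <- length(el_h)
  G <- ctrl$ngauss
  gq <- .gauss01(G)
  bas <- .hermite_basis(gq$x)

  nq <- nel * G                                  # quadrature rows
  # per-row element data (element index varies slowest)
  e_of_row <- rep(seq_len(nel), each = G)
  xi_row <- rep(gq$x, times = nel)
  r_row <- el_r1[e_of_row] + el_h[e_of_row] * xi_row
  h_row <- el_h[e_of_row]
  wt_row <- rep(gq$w, times = nel) * h_row * 2 * pi * r_row
  reg_row <- el_reg[e_of_row]
  ha_row <- regions$h0_upper[reg_row]
  hb_row <- regions$h0_lower[reg_row]

  # local 4-column coefficient blocks (value, d/dr, d2/dr2)
  gi <- rep(seq_len(G), times = nel)
  Vl <- bas$v[gi, , drop = FALSE]
  D1l <- bas$d1[gi, , drop = FALSE] / h_row
  D2l <- bas$d2[gi, , drop = FALSE] / h_row^2
  # derivative DOFs carry d/dr units: scale their shape columns by h
  Vl[, c(2, 4)] <- Vl[, c(2, 4)] * h_row
  D1l[, c(2, 4)] <- D1l[, c(2, 4)] * h_row
  D2l[, c(2, 4)] <- D2l[, c(2, 4)] * h_row

  n1g <- el_n1[e_of_row]                         # global node ids
  dof_cols <- function(field_off) {
    cbind(6L * (n1g - 1L) + field_off, 6L * (n1g - 1L) + field_off + 1L,
          6L * n1g + field_off, 6L * n1g + field_off + 1L)
  }
  mk_op <- function(cols, vals) {
    Matrix::sparseMatrix(i = rep(seq_len(nq), 4L), j = as.vector(cols),
                         x = as.vector(vals), dims = c(nq, ndof))
  }
  cols_a <- dof_cols(1L); cols_b <- dof_cols(3L); cols_M <- dof_cols(5L)
  V_a <- mk_op(cols_a, Vl); D1_a <- mk_op(cols_a, D1l); D2_a <- mk_op(cols_a, D2l)
  V_b <- mk_op(cols_b, Vl); D1_b <- mk_op(cols_b, D1l); D2_b <- mk_op(cols_b, D2l)
  V_M <- mk_op(cols_M, Vl); D1_M <- mk_op(cols_M, D1l)

  Dg <- function(v) Matrix::Diagonal(x = v)
  Div_a <- D1_a + Dg(1 / r_row) %*% V_a
  Div_b <- D1_b + Dg(1 / r_row) %*% V_b
  Divp_a <- D2_a + Dg(1 / r_row) %*% D1_a - Dg(1 / r_row^2) %*% V_a
  Divp_b <- D2_b + Dg(1 / r_row) %*% D1_b - Dg(1 / r_row^2) %*% V_b
  S_a <- D1_M - Dg(ha_row^2 / 2) %*% Divp_a      # H_a'
  S_b <- D1_M + Dg(hb_row^2 / 2) %*% Divp_b      # H_b'
  T_a <- V_a - S_a
  T_b <- V_b + S_b

  quad <- function(op, coef) Matrix::t(op) %*% Dg(coef * wt_row) %*% op
  Q <- quad(Div_a, params$B) + quad(Div_b, params$B) +
    quad(T_a, params$K) + quad(T_b, params$K) +
    quad(S_a, params$sigma) + quad(S_b, params$sigma)
  Q <- Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)

  # ---- constraints -------------------------------------------------------
  # DOF index helper: node id n, field f in 1(a) 2(b) 3(M), deriv 0/1
  dof <- function(n, f, deriv = 0L) 6L * (n - 1L) + 2L * (f - 1L) + 1L + deriv
  ci <- integer(0); cj <- integer(0); cx <- numeric(0)
  dmat <- NULL                                   # rows x 3: (const, n1, n2)
  add_row <- function(cols, vals, d) {
    k <- if (is.null(dmat)) 1L else nrow(dmat) + 1L
    ci <<- c(ci, rep.int(k, length(cols))); cj <<- c(cj, cols); cx <<- c(cx, vals)
    dmat <<- rbind(dmat, d)
  }
  n_wall <- node_off[1] + 1L
  Rp <- geom$Rp
  ha1 <- regions$h0_upper[1]; hb1 <- regions$h0_lower[1]
  # (i) directors at the protein wall
  add_row(dof(n_wall, 1L), 1, c(0, 1, 0))
  add_row(dof(n_wall, 2L), 1, c(0, 0, 1))
  # (ii) hydrophobic thickness matches the protein: H_a - H_b = Hp at Rp
  add_row(c(dof(n_wall, 1L, 0L), dof(n_wall, 1L, 1L),
            dof(n_wall, 2L, 0L), dof(n_wall, 2L, 1L)),
          c(-ha1^2 / 2 / Rp, -ha1^2 / 2, -hb1^2 / 2 / Rp, -hb1^2 / 2),
          c(geom$Hp - ha1 - hb1, 0, 0))
  # (iii) interface matching: directors a, b and neutral surfaces H_a, H_b
  # are continuous.  The intermonolayer surface M is NOT constrained: the
  # leaflets may redistribute thickness across a phase boundary, so M (and
  # with it a', b') carries a free jump fixed by energy minimization.
  # H_a = M + h0a - (h0a^2/2) div a,  H_b = M - h0b + (h0b^2/2) div b.
  if (nreg > 1) {
    for (k in seq_len(nreg - 1L)) {
      nL <- node_off[k] + nn[k]                  # last node of region k
      nR <- node_off[k + 1L] + 1L                # first node of region k+1
      rs <- regions$r_out[k]
      for (f in 1:2) add_row(c(dof(nL, f), dof(nR, f)), c(1, -1), c(0, 0, 0))
      haL <- regions$h0_upper[k]; haR <- regions$h0_upper[k + 1L]
      hbL <- regions$h0_lower[k]; hbR <- regions$h0_lower[k + 1L]
      add_row(c(dof(nL, 3L, 0L), dof(nR, 3L, 0L),
                dof(nL, 1L, 1L), dof(nL, 1L, 0L),
                dof(nR, 1L, 1L), dof(nR, 1L, 0L)),
              c(1, -1,
                -haL^2 / 2, -haL^2 / 2 / rs, haR^2 / 2, haR^2 / 2 / rs),
              c(haR - haL, 0, 0))
      add_row(c(dof(nL, 3L, 0L), dof(nR, 3L, 0L),
                dof(nL, 2L, 1L), dof(nL, 2L, 0L),
                dof(nR, 2L, 1L), dof(nR, 2L, 0L)),
              c(1, -1,
                hbL^2 / 2, hbL^2 / 2 / rs, -hbR^2 / 2, -hbR^2 / 2 / rs),
              c(hbL - hbR, 0, 0))
    }
  }
  # (iv) decay at the truncation radius (gauge M = 0 included)
  n_far <- nnode
  for (f in 1:3) for (dv in 0:1) add_row(dof(n_far, f, dv), 1, c(0, 0, 0))

  C <- Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                            dims = c(nrow(dmat), ndof))

  env <- new.env(parent = emptyenv())
  env$Q <- Q; env$C <- C; env$dmat <- dmat
  env$ndof <- ndof; env$regions <- regions
  env$node_list <- node_list; env$node_off <- node_off; env$nn <- nn
  env$wt_row <- wt_row; env$reg_row <- reg_row
  env$ops <- list(Div_a = Div_a, Div_b = Div_b, T_a = T_a, T_b = T_b,
                  S_a = S_a, S_b = S_b)
  env$params <- params; env$geom <- geom; env$conf <- conf; env$ctrl <- ctrl
  env
}

# Minimize 1/2 x'Qx subject to Cx = d for one or several right-hand sides,
# by eliminating the constraints (null-space method) and factorizing the
# reduced positive-definite Hessian once with a sparse Cholesky.
# Generic linear algebra shared by the Galerkin solver and the
# finite-difference oracle. Returns n x ncol(d) matrix of minimizers.
.min_quadratic <- function(Q, C, d) {
  d <- as.matrix(d)
  n <- ncol(Q)
  m <- nrow(C)
  # constraints touch only a handful of DOFs; pick a well-conditioned basic
  # set by dense column-pivoted QR restricted to those columns
  touched <- which(diff(C@p) > 0L)
  Csub <- as.matrix(C[, touched, drop = FALSE])
  qq <- qr(Csub, LAPACK = TRUE)
  if (qq$rank < m) {
    stop("solver error: singular boundary-condition system ",
         "(rank-deficient constraints)", call. = FALSE)
  }
  piv <- touched[qq$pivot[seq_len(m)]]
  free <- setdiff(seq_len(n), piv)
  B <- as.matrix(C[, piv, drop = FALSE])
  Gf <- C[, free, drop = FALSE]
  # particular solutions: x_piv = B^{ -1 } d, zeros elsewhere
  xp <- matrix(0, n, ncol(d))
  xp[piv, ] <- solve(B, d)
  # null-space map T: x = xp + T z, z the free DOFs
  TB <- -solve(B, as.matrix(Gf))
  nz <- which(abs(TB) > 0, arr.ind = TRUE)
  Tmap <- rbind(
    Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2], x = TB[nz],
                         dims = c(m, length(free))),
    Matrix::Diagonal(length(free))
  )[order(c(piv, free)), , drop = FALSE]
  H <- Matrix::forceSymmetric(Matrix::t(Tmap) %*% Q %*% Tmap)
  rhs <- -Matrix::t(Tmap) %*% (Q %*% xp)
  ch <- tryCatch(Matrix::Cholesky(H, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("solver error: reduced Hessian not positive ",
                        "definite (", conditionMessage(e), ")", call. = FALSE)
                 })
  z <- as.matrix(Matrix::solve(ch, rhs))
  xp + as.matrix(Tmap %*% z)
}

.solve_kkt <- function(env, d) .min_quadratic(env$Q, env$C, d)

#' Elastic energy as a quadratic form in the boundary directors
#'
#' For a fixed region geometry the minimized elastic grand potential is an
#' exact quadratic function of the imposed boundary-director projections:
#' `W(n1, n2) = 1/2 * y' S y` with `y = (1, n1, n2)`.  The 3 x 3 matrix `S`
#' is obtained from three linear solves sharing one factorization, so whole
#' (n1, n2) grids cost no more than a single configuration.
#'
#' @inheritParams build_regions
#' @param ctrl a [solver_control()] list.
#' @return a symmetric 3 x 3 matrix (kBT0), ordering `(1, n1, n2)`.
#' @export
energy_matrix <- function(params, geom, conf, ctrl = solver_control()) {
  env <- .assemble_fem(params, geom, conf, ctrl)
  X <- .solve_kkt(env, env$dmat)                 # ndof x 3 basis solutions
  S <- crossprod(X, as.matrix(env$Q %*% X))
  (S + t(S)) / 2
}

#' Elastic grand potential of one domain configuration
#'
#' Assembles and minimizes the elastic functional for the given protein
#' geometry and ordered-annulus radii; all free coefficients (director
#' values at the domain edges, protein vertical offset) are resolved by the
#' minimization.
#'
#' @inheritParams build_regions
#' @param Rd,Ru ordered-domain radii in the inner / outer leaflet (nm).
#' @param ctrl a [solver_control()] list.
#' @return the elastic grand potential W in kBT0 (a non-negative scalar,
#'   measured from the flat unperturbed state).
#' @export
energy_of_configuration <- function(params, geom, Rd, Ru,
                                    ctrl = solver_control()) {
  conf <- domain_configuration(Rd, Ru, geom)
  S <- energy_matrix(params, geom, conf, ctrl)
  y <- c(1, geom$n1, geom$n2)
  as.numeric(y %*% S %*% y) / 2
}

#' Solve the membrane deformation profile
#'
#' Minimizes the discretized tilt + splay + tension functional subject to
#' the wall conditions (imposed boundary directors, hydrophobic thickness
#' match), interface continuity of directors and neutral surfaces, and decay
#' at infinity, and returns the full radial deformation field.
#'
#' @inheritParams build_regions
#' @param ctrl a [solver_control()] list.
#' @param n_out number of radial sample points per region for the returned
#'   field table.
#' @return an object of class `deformation_profile`; its element `fields` is
#'   a data.frame with columns `r`, `n_a`, `n_b`, `M`, `H_a`, `H_b`, `t_a`,
#'   `t_b`.  Attribute `large_tilt` flags |n| > 1 anywhere (outside the
#'   small-deformation regime).
#' @export
solve_profile <- function(params, geom, conf, ctrl = solver_control(),
                          n_out = 40L) {
  env <- .assemble_fem(params, geom, conf, ctrl)
  d <- env$dmat %*% c(1, geom$n1, geom$n2)
  x <- .solve_kkt(env, d)[, 1]
  fields <- .eval_fields(env, x, n_out)
  large <- max(abs(fields$n_a), abs(fields$n_b)) > 1
  if (large) {
    warning("deformation profile exceeds |n| = 1; ",
            "outside the small-deformation regime", call. = FALSE)
  }
  structure(list(fields = fields, x = x, env = env,
                 params = params, geom = geom, conf = conf),
            class = "deformation_profile", large_tilt = large)
}

# evaluate fields on a per-region output grid from the nodal solution
.eval_fields <- function(env, x, n_out = 40L) {
  out <- NULL
  regions <- env$regions
  for (k in seq_len(nrow(regions))) {
    nd <- env$node_list[[k]]
    rr <- unique(sort(c(nd, seq(nd[1], nd[length(nd)], length.out = n_out))))
    idx <- findInterval(rr, nd, rightmost.closed = TRUE)
    r1 <- nd[idx]; h <- nd[idx + 1L] - nd[idx]
    xi <- (rr - r1) / h
    bas <- .hermite_basis(xi)
    gl_node <- env$node_off[k] + idx
    val <- function(f, der) {
      Bm <- switch(der + 1L, bas$v, bas$d1, bas$d2)
      sc <- switch(der + 1L, 1, 1 / h, 1 / h^2)
      d1 <- x[6L * (gl_node - 1L) + 2L * (f - 1L) + 1L]
      d2 <- x[6L * (gl_node - 1L) + 2L * (f - 1L) + 2L]
      d3 <- x[6L * gl_node + 2L * (f - 1L) + 1L]
      d4 <- x[6L * gl_node + 2L * (f - 1L) + 2L]
      (Bm[, 1] * d1 + Bm[, 2] * h * d2 + Bm[, 3] * d3 + Bm[, 4] * h * d4) * sc
    }
    a <- val(1L, 0L); ap <- val(1L, 1L); app <- val(1L, 2L)
    b <- val(2L, 0L); bp <- val(2L, 1L); bpp <- val(2L, 2L)
    M <- val(3L, 0L); Mp <- val(3L, 1L)
    ha <- regions$h0_upper[k]; hb <- regions$h0_lower[k]
    Da <- ap + a / rr; Db <- bp + b / rr
    Dap <- app + ap / rr - a / rr^2; Dbp <- bpp + bp / rr - b / rr^2
    H_a <- M + ha - ha^2 / 2 * Da
    H_b <- M - hb + hb^2 / 2 * Db
    Sa <- Mp - ha^2 / 2 * Dap; Sb <- Mp + hb^2 / 2 * Dbp
    out <- rbind(out, data.frame(r = rr, n_a = a, n_b = b, M = M,
                                 H_a = H_a, H_b = H_b,
                                 t_a = a - Sa, t_b = b + Sb,
                                 region = k))
  }
  out
}

#' @export
as.data.frame.deformation_profile <- function(x, ...) x$fields

#' @export
print.deformation_profile <- function(x, ...) {
  br <- elastic_energy(x)
  cat("Membrane deformation profile\n")
  cat(sprintf("  protein: Rp = %g nm, Hp = %g nm, n1 = %+g, n2 = %+g\n",
              x$geom$Rp, x$geom$Hp, x$geom$n1, x$geom$n2))
  cat(sprintf("  domain:  Ru = %g nm, Rd = %g nm; %d region(s)\n",
              x$conf$Ru, x$conf$Rd, nrow(x$env$regions)))
  cat(sprintf("  elastic grand potential W = %.4f kBT0\n", br$W_total))
  if (isTRUE(attr(x, "large_tilt")))
    cat("  warning: |n| exceeds 1 somewhere (large-deformation regime)\n")
  invisible(x)
}

#' @export
plot.deformation_profile <- function(x, ...) {
  f <- x$fields
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  matplot(f$r, cbind(f$n_a, f$n_b), type = "l", lty = 1,
          col = c("firebrick", "steelblue"),
          xlab = "r (nm)", ylab = "director projection", ...)
  legend("topright", c("outer n_a", "inner n_b"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  matplot(f$r, cbind(f$H_a, f$M, f$H_b), type = "l", lty = 1,
          col = c("firebrick", "grey40", "steelblue"),
          xlab = "r (nm)", ylab = "surface height (nm)", ...)
  legend("right", c("H_a", "M", "H_b"), lty = 1,
         col = c("firebrick", "grey40", "steelblue"), bty = "n")
  invisible(x)
}

#' Elastic energy breakdown of a solved profile
#'
#' Integrates the bending (splay), tilt and tension contributions of each
#' leaflet over each region for a solved [solve_profile()] result.
#'
#' @param profile a `deformation_profile`.
#' @param params ignored; retained so the breakdown can be requested with
#'   the signature `(profile, params)`. The profile carries its parameters.
#' @return an object of class `energy_breakdown`: list with `W_total` (kBT0)
#'   and `components`, a data.frame over region, leaflet and deformation
#'   mode.
#' @export
elastic_energy <- function(profile, params = NULL) {
  env <- profile$env
  x <- profile$x
  p <- profile$params
  comp <- NULL
  modes <- list(
    list(op = "Div_a", coef = p$B, leaflet = "outer", mode = "bending"),
    list(op = "Div_b", coef = p$B, leaflet = "inner", mode = "bending"),
    list(op = "T_a", coef = p$K, leaflet = "outer", mode = "tilt"),
    list(op = "T_b", coef = p$K, leaflet = "inner", mode = "tilt"),
    list(op = "S_a", coef = p$sigma, leaflet = "outer", mode = "tension"),
    list(op = "S_b", coef = p$sigma, leaflet = "inner", mode = "tension")
  )
  for (m in modes) {
    q <- as.numeric(env$ops[[m$op]] %*% x)
    e_row <- 0.5 * m$coef * env$wt_row * q^2
    e_reg <- tapply(e_row, env$reg_row, sum)
    comp <- rbind(comp, data.frame(region = as.integer(names(e_reg)),
                                   leaflet = m$leaflet, mode = m$mode,
                                   energy = as.numeric(e_reg)))
  }
  structure(list(W_total = sum(comp$energy), components = comp),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("Elastic grand potential W = %.4f kBT0\n", x$W_total))
  agg <- stats::aggregate(energy ~ mode + leaflet, data = x$components, sum)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-7s %-6s %10.4f kBT0\n", agg$mode[i], agg$leaflet[i],
                agg$energy[i]))
  }
  invisible(x)
}
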