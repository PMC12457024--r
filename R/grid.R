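# 1-D two-layer mesh and finite-difference weight machinery.

#' Build the computational mesh over choroid and sclera
#'
#' Nodes span `[0, L_C + L_S]` with the choroid–sclera interface (`x = L_C`)
#' as an exact node. The choroidal mesh is graded towards `x = alpha * L_C`,
#' where the smoothed-step capillary density falls off, so that the
#' transition (90% to 10% of the plateau, width `~4.4 L_C / Gamma`) is
#' resolved by many nodes even at modest totals; the sclera is meshed
#' uniformly.
#'
#' @param params an [atra_params()] object.
#' @param n_choroid,n_sclera number of intervals per layer (default 400 each).
#' @param refine local refinement factor applied around the capillary
#'   step transition.
#' @return An object of class `atra_grid`: list with node positions `x`,
#'   interface index `i_if`, layer factor, and node counts.
#' @export
make_grid <- function(params, n_choroid = 400, n_sclera = 400, refine = 4) {
  stopifnot(n_choroid >= 20, n_sclera >= 10)
  L_C <- params$L_C
  L_S <- params$L_S
  x0 <- params$alpha * L_C
  s <- 5 / params$Gamma # Gaussian grading width, in units of L_C
  # node density on a fine auxiliary mesh; invert its CDF for node placement
  xi <- seq(0, 1, length.out = 8192)
  w <- 1 + refine * exp(-((xi - params$alpha) / s)^2)
  cw <- cumsum(c(0, (w[-1] + w[-length(w)]) / 2 * diff(xi)))
  cw <- cw / cw[length(cw)]
  xc <- stats::approx(cw, xi, xout = seq(0, 1, length.out = n_choroid + 1))$y * L_C
  xc[1] <- 0
  xc[length(xc)] <- L_C
  xs <- seq(L_C, L_C + L_S, length.out = n_sclera + 1)
  x <- c(xc, xs[-1])
  g <- structure(
    list(
      x = x, i_if = n_choroid + 1L, n_choroid = as.integer(n_choroid),
      n_sclera = as.integer(n_sclera), L_C = L_C, L_S = L_S,
      x_transition = x0
    ),
    class = "atra_grid"
  )
  g$ops <- .grid_operators(g)
  g
}

# Precomputed stencil weights: interior 3-point first/second derivative
# triplets (interface node excluded; it carries matching conditions), the
# four one-sided second-order boundary/interface stencils, and layer-wise
# sparse gradient operators for post-processing.
.grid_operators <- function(grid) {
  x <- grid$x
  N <- length(x)
  i_if <- grid$i_if
  int_nodes <- setdiff(2:(N - 1L), i_if)
  h1 <- x[int_nodes] - x[int_nodes - 1L]
  h2 <- x[int_nodes + 1L] - x[int_nodes]
  w1 <- cbind(-h2 / (h1 * (h1 + h2)), (h2 - h1) / (h1 * h2), h1 / (h2 * (h1 + h2)))
  w2 <- cbind(2 / (h1 * (h1 + h2)), -2 / (h1 * h2), 2 / (h2 * (h1 + h2)))
  ii_int <- rep(int_nodes, 3L)
  jj_int <- c(int_nodes - 1L, int_nodes, int_nodes + 1L)
  bc0 <- list(idx = 1:3, w = fd_weights(x[1:3], x[1], 1))
  ifm <- list(idx = i_if - (0:2), w = fd_weights(x[i_if - (0:2)], x[i_if], 1))
  ifp <- list(idx = i_if + (0:2), w = fd_weights(x[i_if + (0:2)], x[i_if], 1))
  bcN <- list(idx = N - (0:2), w = fd_weights(x[N - (0:2)], x[N], 1))

  grad_layer <- function(lo, hi, first, last) {
    rows <- integer(0); cols <- integer(0); w <- numeric(0)
    ids <- lo:hi
    interior <- ids[ids > lo & ids < hi]
    hh1 <- x[interior] - x[interior - 1L]
    hh2 <- x[interior + 1L] - x[interior]
    rows <- c(
      rep(first$row, 3L), rep(interior - lo + 1L, 3L), rep(last$row, 3L)
    )
    cols <- c(first$idx, interior - 1L, interior, interior + 1L, last$idx)
    w <- c(
      first$w,
      -hh2 / (hh1 * (hh1 + hh2)), (hh2 - hh1) / (hh1 * hh2), hh1 / (hh2 * (hh1 + hh2)),
      last$w
    )
    Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(hi - lo + 1L, N))
  }
  G_cho <- grad_layer(1L, i_if,
    first = list(row = 1L, idx = bc0$idx, w = bc0$w),
    last = list(row = i_if, idx = ifm$idx, w = ifm$w)
  )
  G_scl <- grad_layer(i_if, N,
    first = list(row = 1L, idx = ifp$idx, w = ifp$w),
    last = list(row = N - i_if + 1L, idx = bcN$idx, w = bcN$w)
  )
  list(
    int_nodes = int_nodes, ii_int = ii_int, jj_int = jj_int,
    w1_int = as.numeric(w1), w2_int = as.numeric(w2),
    bc0 = bc0, ifm = ifm, ifp = ifp, bcN = bcN,
    G_cho = G_cho, G_scl = G_scl
  )
}

#' @export
print.atra_grid <- function(x, ...) {
  cat("<atra_grid> ", length(x$x), " nodes (", x$n_choroid, " choroid + ",
    x$n_sclera, " sclera intervals), interface at node ", x$i_if, "\n",
    sep = ""
  )
  invisible(x)
}

# Fornberg (1988) finite-difference weights for the m-th derivative at x0
# on an arbitrary stencil z. Returns a weight vector the length of z.
fd_weights <- function(z, x0, m) {
  n <- length(z)
  c_mat <- matrix(0, n, m + 1)
  c1 <- 1
  c4 <- z[1] - x0
  c_mat[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1
    c5 <- c4
    c4 <- z[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- z[i] - z[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        if (mn >= 1) {
          for (k in mn:1) {
            c_mat[i, k + 1] <- c1 * (k * c_mat[i - 1, k] - c5 * c_mat[i - 1, k + 1]) / c2
          }
        }
        c_mat[i, 1] <- -c1 * c5 * c_mat[i - 1, 1] / c2
      }
      if (mn >= 1) {
        for (k in mn:1) {
          c_mat[j, k + 1] <- (c4 * c_mat[j, k + 1] - k * c_mat[j, k]) / c3
        }
      }
      c_mat[j, 1] <- c4 * c_mat[j, 1] / c3
    }
    c1 <- c2
  }
  c_mat[, m + 1]
}

# trapezoidal quadrature on arbitrary nodes
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
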