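# Two-layer Darcy flow with Starling filtration and the Goldmann closure.
#
# For frozen tissue-albumin concentrations the pressure problem is linear in
# (p, IOP), so the boundary-value problem and the scalar Goldmann balance are
# assembled as one augmented sparse linear system: no shooting iteration.

#' Unconventional outflow from the Goldmann aqueous-humour balance
#'
#' `Q_u(IOP) = Q_prod - C_fac * (IOP - EVP)`: aqueous humour not drained by
#' the conventional (trabecular) route leaves via the unconventional pathway.
#'
#' @param iop intraocular pressure (Pa).
#' @param params an [atra_params()] object.
#' @return volumetric unconventional outflow (m^3 s^-1).
#' @export
goldmann_outflow <- function(iop, params) {
  params$Q_prod - params$C_fac * (iop - params$EVP)
}

#' Starling transmural filtration source in the choroid
#'
#' `q_C(x) = a(x) * Lp_star * [(p_B - p) - sigma * R * T * (c_B_tot - c_tot)]`
#' with `p_B = IOP + dP_blood`. Positive values mean net fluid loss from the
#' filtering capillaries into the extravascular tissue.
#'
#' @param x positions in the choroid (m).
#' @param p local tissue pressure (Pa), recycled to the length of `x`.
#' @param c_total local tissue albumin concentration, SA + atRA:SA
#'   (mol m^-3).
#' @param iop intraocular pressure (Pa).
#' @param params an [atra_params()] object.
#' @return volumetric source per unit tissue volume (s^-1).
#' @export
starling_source <- function(x, p, c_total, iop, params) {
  a <- capillary_density(x, params)
  p_B <- iop + params$dP_blood
  osm <- params$sigma * params$R_gas * params$T_abs *
    (params$c_SA_blood_total - c_total)
  a * params$Lp_star * ((p_B - p) - osm)
}

#' Solve the steady fluid problem with self-consistent IOP
#'
#' Solves the two-layer pressure boundary-value problem: in the choroid
#' `d2p/dx2 = -(mu/K_C) q_C` with the Starling source, in the sclera
#' `d2p/dx2 = 0`; RPE pumping flux at `x = 0`, pressure continuity and a
#' velocity jump `Q_u/A_S` (unconventional inflow through the suprachoroidal
#' space) at the interface, orbital pressure at the outer scleral surface.
#' The intraocular pressure is an additional scalar unknown closed by
#' `p(L_C) = IOP - dP_SCS` together with the Goldmann balance, all assembled
#' in one augmented sparse linear system.
#'
#' @param params an [atra_params()] object.
#' @param grid an [make_grid()] object.
#' @param c_total tissue albumin profile (mol m^-3) on the grid nodes, or
#'   `NULL` for a zero osmotic pressure difference (tissue concentration
#'   equal to blood).
#' @return An object of class `fluid_solution`: profile vectors `x`, `p`
#'   (Pa), `q` (s^-1, zero in the sclera), layer-wise superficial velocities
#'   `u_choroid` (nodes `1..i_if`) and `u_sclera` (nodes `i_if..N`), scalars
#'   `iop` (Pa), `Q_u` (m^3 s^-1), `p_B` (Pa).
#' @export
solve_fluid <- function(params, grid, c_total = NULL) {
  stopifnot(inherits(grid, "atra_grid"))
  x <- grid$x
  N <- length(x)
  i_if <- grid$i_if
  if (abs(x[i_if] - params$L_C) > 1e-9 * params$L_C) {
    rlang::abort("grid interface node does not match L_C of the parameter set",
      class = "atraflux_precondition_error"
    )
  }
  if (is.null(c_total)) c_total <- rep(params$c_SA_blood_total, N)
  if (length(c_total) != N) {
    rlang::abort("c_total must be defined on the grid nodes",
      class = "atraflux_precondition_error"
    )
  }

  mu <- params$mu
  K_C <- params$K_C
  K_S <- params$K_S
  a <- c(capillary_density(x[1:i_if], params), rep(0, N - i_if))
  osm <- params$sigma * params$R_gas * params$T_abs *
    (params$c_SA_blood_total - c_total)

  # unknowns: p_1..p_N, IOP (index N+1); vectorized triplet assembly from
  # the precomputed grid stencil operators
  ops <- grid$ops
  rhs <- numeric(N + 1)
  k_node <- (mu / K_C) * a * params$Lp_star # zero beyond the choroid
  k_int <- k_node[ops$int_nodes]
  n_int <- length(ops$int_nodes)

  ii <- c(
    ops$ii_int, # interior p'' stencils
    ops$int_nodes, ops$int_nodes, # -k_i p_i and +k_i IOP
    rep(1L, 3L), # RPE flux BC
    rep(i_if, 7L), # interface flux matching + IOP column
    N, # outer Dirichlet
    N + 1L, N + 1L # IOP closure
  )
  jj <- c(
    ops$jj_int,
    ops$int_nodes, rep(N + 1L, n_int),
    ops$bc0$idx,
    ops$ifm$idx, ops$ifp$idx, N + 1L,
    N,
    i_if, N + 1L
  )
  vv <- c(
    ops$w2_int,
    -k_int, k_int,
    ops$bc0$w,
    -(K_C / mu) * ops$ifm$w, (K_S / mu) * ops$ifp$w, -params$C_fac / params$A_S,
    1,
    1, -1
  )
  rhs[ops$int_nodes] <- k_int * (osm[ops$int_nodes] - params$dP_blood)
  rhs[1] <- -mu * params$u_RPE / K_C
  rhs[i_if] <- -(params$Q_prod + params$C_fac * params$EVP) / params$A_S
  rhs[N] <- params$p_orbit
  rhs[N + 1L] <- -params$dP_SCS

  # row equilibration: rows mix O(1/h^2) Laplacian and O(C_fac/A_S) flow
  # balance entries, so scale each row to unit max magnitude before the LU
  rs <- tapply(abs(vv), ii, max)
  scale_row <- as.numeric(rs[as.character(seq_len(N + 1L))])
  vv <- vv / scale_row[ii]
  rhs <- rhs / scale_row
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N + 1L, N + 1L))
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)), error = function(e) {
    rlang::abort(paste0("fluid linear system could not be solved: ", conditionMessage(e)),
      class = "atraflux_solver_error"
    )
  })
  p <- sol[1:N]
  iop <- sol[N + 1L]
  Q_u <- goldmann_outflow(iop, params)

  # residual check on the augmented system
  res <- max(abs(A %*% sol - rhs)) / max(1, max(abs(rhs)))
  if (!is.finite(iop) || res > 1e-8) {
    rlang::abort(sprintf("fluid solve did not converge (relative residual %.3e)", res),
      class = "atraflux_solver_error"
    )
  }

  q <- numeric(N)
  q[1:i_if] <- starling_source(x[1:i_if], p[1:i_if], c_total[1:i_if], iop, params)

  # layer-wise velocities from Darcy's law via the precomputed gradients
  u_choroid <- -(K_C / mu) * as.numeric(ops$G_cho %*% p)
  u_sclera <- -(K_S / mu) * as.numeric(ops$G_scl %*% p)

  structure(
    list(
      x = x, p = p, q = q, u_choroid = u_choroid, u_sclera = u_sclera,
      iop = iop, Q_u = Q_u, p_B = iop + params$dP_blood,
      i_if = i_if, c_total = c_total
    ),
    class = "fluid_solution"
  )
}

#' @export
print.fluid_solution <- function(x, ...) {
  cat(sprintf(
    "<fluid_solution> IOP = %.3f mmHg, Q_u = %.3e m^3/s, %d nodes\n",
    x$iop / MMHG_PA, x$Q_u, length(x$x)
  ))
  invisible(x)
}

#' Tidy a fluid solution into a per-node tibble
#'
#' The interface node appears twice (once per layer) because the superficial
#' velocity jumps there by `Q_u/A_S`.
#'
#' @param x a `fluid_solution`.
#' @param ... unused.
#' @return tibble with columns `x`, `layer`, `p_Pa`, `p_mmHg`, `u`, `q`.
#' @export
tidy.fluid_solution <- function(x, ...) {
  i_if <- x$i_if
  N <- length(x$x)
  sol <- x
  p_Pa <- c(sol$p[1:i_if], sol$p[i_if:N])
  tibble::tibble(
    x = c(sol$x[1:i_if], sol$x[i_if:N]),
    layer = rep(c("choroid", "sclera"), c(i_if, N - i_if + 1L)),
    p_Pa = p_Pa,
    p_mmHg = p_Pa / MMHG_PA,
    u = c(sol$u_choroid, sol$u_sclera),
    q = c(sol$q[1:i_if], sol$q[i_if:N])
  )
}

#' One-row scalar summary of a fluid solution
#'
#' @param x a `fluid_solution`.
#' @param ... unused.
#' @export
glance.fluid_solution <- function(x, ...) {
  tibble::tibble(
    iop_mmHg = x$iop / MMHG_PA,
    Q_u = x$Q_u,
    u_sclera_out = x$u_sclera[length(x$u_sclera)],
    u_CC = trapz(x$x[1:x$i_if], x$q[1:x$i_if])
  )
}

#' Partition drained fluid between uveovortex and uveoscleral routes
#'
#' All fluid entering the domain (RPE pumping plus unconventional inflow at
#' the suprachoroidal space) leaves either by reabsorption into the
#' choriocapillaris (uveovortex route) or across the sclera into the orbit
#' (uveoscleral route).
#'
#' @param fluid a converged [solve_fluid()] solution.
#' @param params the matching [atra_params()] object.
#' @return tibble with the two volumetric flows (m^3 s^-1), their fractions
#'   of total drainage, and the choriocapillaris-to-sclera drainage ratio.
#' @export
partition_outflow <- function(fluid, params) {
  i_if <- fluid$i_if
  uveoscleral <- params$A_S * fluid$u_sclera[length(fluid$u_sclera)]
  u_CC <- trapz(fluid$x[1:i_if], fluid$q[1:i_if]) # signed; <0 = net absorption
  uveovortex <- -params$A_S * u_CC
  total <- uveoscleral + uveovortex
  tibble::tibble(
    uveoscleral = uveoscleral,
    uveovortex = uveovortex,
    uveoscleral_fraction = uveoscleral / total,
    uveovortex_fraction = uveovortex / total,
    drainage_ratio = uveovortex / uveoscleral
  )
}
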