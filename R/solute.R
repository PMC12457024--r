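# Steady advection-diffusion-reaction transport of serum albumin (SA,
# species 2) and the atRA:SA complex (species 3) on a frozen fluid field.
#
# Free atRA is never a transported state: binding equilibrates fast and only
# 0.2-1.5% of atRA is unbound, so newly synthesized atRA appears directly as
# a +k_prod*a(x) source for atRA:SA (and a matching -k_prod*a(x) sink for
# free SA). The scleral CYP26 sink is nonlinear in c3 through its induction
# bracket and is resolved by Picard iteration with under-relaxation.

#' CYP26-mediated atRA degradation rate in the sclera
#'
#' Consumption magnitude
#' `r = k_CYP_deg * Ind_max * (c3/f_u_inc) / (Ind_C50 + c3/f_u_inc) * c3`:
#' first-order degradation whose effective rate constant is induced by the
#' local atRA:SA concentration with a saturating (half-saturation `Ind_C50`)
#' fold-induction up to `Ind_max`.
#'
#' @param c3 atRA:SA concentration (mol m^-3), nonnegative.
#' @param params an [atra_params()] object.
#' @return consumption rate (mol m^-3 s^-1), applied with a negative sign in
#'   the atRA:SA equation and a positive sign in the free-SA equation.
#' @export
degradation_rate <- function(c3, params) {
  if (any(c3 < 0)) {
    rlang::abort("concentration must be nonnegative", class = "atraflux_domain_error")
  }
  cs <- c3 / params$f_u_inc
  params$k_CYP_deg * params$Ind_max * cs / (params$Ind_C50 + cs) * c3
}

# induced first-order rate constant g(c3) such that r = g * c3
.induced_rate <- function(c3, params) {
  cs <- pmax(c3, 0) / params$f_u_inc
  params$k_CYP_deg * params$Ind_max * cs / (params$Ind_C50 + cs)
}

#' Equilibrium unbound fraction of atRA
#'
#' At binding equilibrium with association constant `Ka` and free-albumin
#' concentration `c2`, the unbound fraction of total atRA is
#' `1 / (1 + Ka * c2)`.
#'
#' @param Ka association constant (M^-1).
#' @param c2 free serum-albumin concentration (M).
#' @return dimensionless fraction in (0, 1].
#' @export
#' @examples
#' unbound_fraction(2.3e6, 2e-4) # ~0.2%
unbound_fraction <- function(Ka, c2) {
  stopifnot(all(Ka >= 0), all(c2 >= 0))
  1 / (1 + Ka * c2)
}

#' Transmural solute exchange between blood and choroidal tissue
#'
#' `b_i = beta * (c_i_blood - c_i_tissue) * a(x)` in the choroid; zero in the
#' sclera (no vessels leak there). Negative values mean back-leakage from
#' tissue into the choroidal circulation.
#'
#' @param x positions in the choroid (m).
#' @param c_tissue local tissue concentration (mol m^-3).
#' @param c_blood blood concentration (mol m^-3).
#' @param params an [atra_params()] object.
#' @return volumetric exchange rate (mol m^-3 s^-1).
#' @export
transmural_exchange <- function(x, c_tissue, c_blood, params) {
  params$beta * (c_blood - c_tissue) * capillary_density(x, params)
}

# Transport operator for one species on a frozen fluid field:
#   rows: no-flux at x=0, interior d(uc)/dx - D c'', total-flux matching at
#   the interface, zero gradient at the outer boundary.
# The reaction/exchange decay terms enter later as a diagonal contribution,
# so this matrix is built once per fluid field and reused across the Picard
# iterations on the nonlinear CYP26 sink.
.species_transport <- function(grid, u_choroid, u_sclera, D_C, D_S) {
  x <- grid$x
  N <- length(x)
  i_if <- grid$i_if
  ops <- grid$ops

  # layer-wise velocity indexed by node, per side of the interface
  u_cho_full <- c(u_choroid, rep(NA_real_, N - i_if))
  u_scl_full <- c(rep(NA_real_, i_if - 1L), u_sclera)
  u_stencil <- ifelse(rep(ops$int_nodes < i_if, 3L), u_cho_full[ops$jj_int],
    u_scl_full[ops$jj_int]
  )
  D_int <- ifelse(rep(ops$int_nodes < i_if, 3L), D_C, D_S)

  ii <- c(
    ops$ii_int, ops$ii_int, # advection + diffusion stencils
    1L, rep(1L, 3L), # RPE no-flux
    i_if, rep(i_if, 6L), # interface flux matching
    rep(N, 3L) # outer zero gradient
  )
  jj <- c(
    ops$jj_int, ops$jj_int,
    1L, ops$bc0$idx,
    i_if, ops$ifm$idx, ops$ifp$idx,
    ops$bcN$idx
  )
  vv <- c(
    ops$w1_int * u_stencil, -D_int * ops$w2_int,
    u_choroid[1], -D_C * ops$bc0$w,
    u_choroid[i_if] - u_sclera[1], -D_C * ops$ifm$w, D_S * ops$ifp$w,
    ops$bcN$w
  )
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
}

# Solve (T + diag(decay)) c = src with row equilibration.
.solve_species <- function(transport, decay, src) {
  A <- transport
  Matrix::diag(A) <- Matrix::diag(A) + decay
  rs <- Matrix::rowSums(abs(A))
  A <- Matrix::Diagonal(x = 1 / rs) %*% A
  as.numeric(Matrix::solve(A, src / rs))
}

#' Solve steady SA and atRA:SA transport on a fluid field
#'
#' Solves, per layer, `d(u c_i)/dx - D_i c_i'' = r_i + b_i` for SA (i = 2)
#' and atRA:SA (i = 3). Sources: choroidal synthesis `+k_prod a(x)` for
#' atRA:SA (mirrored as a free-SA sink), transmural leakage
#' `beta (c_iB - c_i) a(x)` for both species in the choroid, and the induced
#' CYP26 sink in the sclera (atRA:SA consumed, free SA released). The
#' nonlinear sink is resolved by under-relaxed Picard iteration on the
#' induction bracket to a relative tolerance of 1e-10.
#'
#' @param params an [atra_params()] object.
#' @param grid the [make_grid()] mesh the fluid field was solved on.
#' @param fluid a converged [solve_fluid()] solution.
#' @param include_atra solve the atRA:SA species (default `TRUE`); with
#'   `FALSE` only SA is transported and `c3` is identically zero (useful for
#'   fluid/SA-only studies where atRA is a passive tracer).
#' @param tol relative Picard tolerance on the c3 profile.
#' @param max_iter Picard iteration cap.
#' @param check abort on negative concentrations beyond discretization
#'   round-off (disabled for intermediate iterates of the osmotic coupling,
#'   whose transients may be unphysical; negative values are clamped either
#'   way).
#' @param g_init warm start for the induced degradation-rate profile
#'   (typically from the previous osmotic coupling iterate).
#' @return An object of class `solute_solution` with concentration profiles
#'   `c2`, `c3` (mol m^-3), per-species advective/diffusive flux profiles,
#'   the scleral degradation-rate profile `r3` (mol m^-3 s^-1, consumption
#'   magnitude, zero in the choroid), and the Picard iteration count.
#' @export
solve_solute <- function(params, grid, fluid, include_atra = TRUE,
                         tol = 1e-10, max_iter = 400, check = TRUE,
                         g_init = NULL) {
  stopifnot(inherits(fluid, "fluid_solution"))
  x <- grid$x
  N <- length(x)
  i_if <- grid$i_if
  a <- c(capillary_density(x[1:i_if], params), rep(0, N - i_if))
  sclera <- seq_len(N) > i_if
  c2_B <- params$c_SA_blood_total - params$c3_B
  c3_B <- params$c3_B

  T3 <- .species_transport(grid, fluid$u_choroid, fluid$u_sclera,
    params$D3_C, params$D3_S)
  T2 <- if (params$D2_C == params$D3_C && params$D2_S == params$D3_S) {
    T3
  } else {
    .species_transport(grid, fluid$u_choroid, fluid$u_sclera,
      params$D2_C, params$D2_S)
  }
  interior <- seq_len(N) > 1L & seq_len(N) < N & seq_len(N) != i_if

  # --- atRA:SA (species 3): nonlinear scleral sink, independent of c2 ---
  iterations <- 0L
  if (include_atra) {
    # frozen induced rate constant on sclera nodes; warm-startable across
    # osmotic coupling iterations
    g <- if (is.null(g_init)) numeric(N) else g_init
    c3 <- numeric(N)
    relax <- 1
    dc_prev <- Inf
    src3 <- (params$k_prod * a + params$beta * a * c3_B) * interior
    repeat {
      decay <- (params$beta * a + g * sclera) * interior
      c3_new <- .solve_species(T3, decay, src3)
      iterations <- iterations + 1L
      dc <- max(abs(c3_new - c3)) / max(max(abs(c3_new)), 1e-300)
      c3 <- c3_new
      # under-relax only when the iteration stops contracting
      if (dc > 0.7 * dc_prev) relax <- max(relax / 2, 0.25)
      dc_prev <- dc
      g_target <- .induced_rate(c3, params) * sclera
      g <- relax * g_target + (1 - relax) * g
      if (dc < tol) break
      if (iterations >= max_iter) {
        rlang::abort(
          sprintf(
            "CYP26 Picard iteration did not converge in %d iterations (last relative change %.3e)",
            max_iter, dc
          ),
          class = "atraflux_solver_error"
        )
      }
    }
    if (check && min(c3) < -1e-8 * max(abs(c3))) {
      rlang::abort("negative atRA:SA concentrations beyond discretization round-off",
        class = "atraflux_solver_error"
      )
    }
    c3 <- pmax(c3, 0)
    # reported consumption profile: the sink acts on the open scleral
    # interval, but its scleral-side limit at the interface node is nonzero
    # and must be included for second-order quadrature of the consumption
    # integral
    r3 <- .induced_rate(c3, params) * c3 * (seq_len(N) >= i_if)
  } else {
    c3 <- numeric(N)
    r3 <- numeric(N)
    g <- numeric(N)
  }

  # --- SA (species 2): linear given c3 ---
  decay2 <- params$beta * a * interior
  # choroidal binding sink -k_prod*a and scleral release +r3 of free SA
  src2 <- (-params$k_prod * a + params$beta * a * c2_B + r3) * interior
  c2 <- .solve_species(T2, decay2, src2)
  if (check && min(c2) < -1e-8 * max(abs(c2))) {
    rlang::abort("negative SA concentrations beyond discretization round-off",
      class = "atraflux_solver_error"
    )
  }
  c2 <- pmax(c2, 0)

  # flux decomposition on a single per-node profile (interface row keeps the
  # choroid-side velocity and gradient)
  grad_full <- function(c) {
    gc <- as.numeric(grid$ops$G_cho %*% c)
    gs <- as.numeric(grid$ops$G_scl %*% c)
    c(gc, gs[-1])
  }
  flux <- function(c, D_C, D_S) {
    u_node <- c(fluid$u_choroid, fluid$u_sclera[-1])
    D_node <- c(rep(D_C, i_if), rep(D_S, N - i_if))
    list(adv = u_node * c, diff = -D_node * grad_full(c))
  }
  f2 <- flux(c2, params$D2_C, params$D2_S)
  f3 <- flux(c3, params$D3_C, params$D3_S)

  structure(
    list(
      x = x, c2 = c2, c3 = c3,
      J_adv_2 = f2$adv, J_diff_2 = f2$diff,
      J_adv_3 = f3$adv, J_diff_3 = f3$diff,
      r3 = r3, g = g, i_if = i_if, iterations = iterations
    ),
    class = "solute_solution"
  )
}

#' @export
print.solute_solution <- function(x, ...) {
  cat(sprintf(
    "<solute_solution> %d nodes, %d Picard iterations; c3 range [%.3g, %.3g] nM\n",
    length(x$x), x$iterations, min(x$c3) / NM_MOLM3, max(x$c3) / NM_MOLM3
  ))
  invisible(x)
}

#' Tidy a solute solution into a per-node tibble
#'
#' @param x a `solute_solution`.
#' @param ... unused.
#' @return tibble with positions, layer, concentrations in mM (SA) and nM
#'   (atRA:SA), flux decompositions (mol m^-2 s^-1) and the scleral
#'   degradation-rate profile.
#' @export
tidy.solute_solution <- function(x, ...) {
  sol <- x
  layer <- rep("choroid", length(sol$x))
  layer[seq_along(sol$x) > sol$i_if] <- "sclera"
  tibble::tibble(
    x = sol$x, layer = layer,
    c2_mM = sol$c2 / MM_MOLM3,
    c3_nM = sol$c3 / NM_MOLM3,
    J_adv_SA = sol$J_adv_2, J_diff_SA = sol$J_diff_2,
    J_adv_atRA = sol$J_adv_3, J_diff_atRA = sol$J_diff_3,
    r3 = sol$r3
  )
}
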