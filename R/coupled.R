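# Fixed-point coupling of the fluid and solute solvers via the osmotic
# pressure of the tissue albumin pool, and the scalar summary observables.

#' Solve the coupled steady-state fluid + solute problem
#'
#' Alternates [solve_fluid()] (with the tissue albumin profile `c2 + c3`
#' feeding back into the Starling filtration term) and [solve_solute()]
#' until the intraocular pressure changes by less than `tol_iop` and the
#' concentration profiles by less than `tol_conc` (relative). The first
#' fluid solve uses a zero osmotic gradient (tissue concentration equal to
#' blood), which gives a physically sensible starting IOP.
#'
#' @param params an [atra_params()] object.
#' @param grid a [make_grid()] mesh; defaults to the standard 400 + 400
#'   interval mesh for the parameter set.
#' @param include_atra solve atRA:SA transport (default `TRUE`); `FALSE`
#'   restricts the model to fluid + SA.
#' @param tol_iop IOP convergence tolerance (mmHg).
#' @param tol_conc relative concentration-profile convergence tolerance.
#' @param max_iter coupling iteration cap.
#'   `tol_conc` is measured against the blood albumin concentration scale.
#' @param check abort if the converged state carries negative concentrations
#'   beyond discretization round-off (see [solve_solute()]). Disabling
#'   accepts converged fixed points in unphysical parameter regimes (for
#'   example reversed scleral flow at extreme sensitivity-analysis corners),
#'   with concentrations clamped at zero.
#' @return An object of class `atra_model`: list with elements `fluid`
#'   ([solve_fluid()] result), `solute` ([solve_solute()] result), `summary`
#'   (one-row tibble, see [summarize_model()]), `params`, `grid`, and the
#'   coupling iteration count. Deterministic for fixed inputs and grid.
#' @export
#' @examples
#' \donttest{
#' fit <- solve_steady_state(atra_params("mouse"), make_grid(atra_params("mouse"), 100, 100))
#' glance(fit)$iop_mmHg
#' }
solve_steady_state <- function(params, grid = make_grid(params),
                               include_atra = TRUE,
                               tol_iop = 1e-6, tol_conc = 1e-8,
                               max_iter = 80, check = TRUE) {
  validate_params(params)
  c_total <- rep(params$c_SA_blood_total, length(grid$x))
  iop_prev <- NA_real_
  d_c_prev <- Inf
  relax <- 0.5
  history <- numeric(0)
  g_warm <- NULL
  for (it in seq_len(max_iter)) {
    fluid <- solve_fluid(params, grid, c_total)
    solute <- solve_solute(params, grid, fluid,
      include_atra = include_atra, check = FALSE, g_init = g_warm
    )
    g_warm <- solute$g
    c_new <- solute$c2 + solute$c3
    d_iop <- if (is.na(iop_prev)) Inf else abs(fluid$iop - iop_prev) / MMHG_PA
    # profile change scaled by the fixed blood albumin level (robust in
    # degenerate zero-concentration limits)
    d_c <- max(abs(c_new - c_total)) / params$c_SA_blood_total
    history <- c(history, fluid$iop / MMHG_PA)
    iop_prev <- fluid$iop
    # start damped (the first iterates can overshoot into unphysical
    # states); damp further if the residual stops contracting, speed back
    # up while it contracts strongly
    if (d_c > 0.7 * d_c_prev) {
      relax <- max(relax / 2, 0.125)
    } else if (d_c < 0.2 * d_c_prev) {
      relax <- min(1, 1.5 * relax)
    }
    d_c_prev <- d_c
    c_total <- relax * c_new + (1 - relax) * c_total
    if (d_iop < tol_iop && d_c < tol_conc) break
    if (it == max_iter) {
      rlang::abort(
        paste0(
          "osmotic coupling did not converge in ", max_iter,
          " iterations; IOP iterates (mmHg): ",
          paste(sprintf("%.6f", utils::tail(history, 8)), collapse = ", ")
        ),
        class = "atraflux_solver_error"
      )
    }
  }
  # final consistent pass so fluid and solute share the converged c_total
  fluid <- solve_fluid(params, grid, c_total)
  solute <- solve_solute(params, grid, fluid,
    include_atra = include_atra, check = check, g_init = g_warm
  )
  structure(
    list(
      fluid = fluid, solute = solute,
      summary = summarize_model(fluid, solute, params),
      params = params, grid = grid, coupling_iterations = it,
      iop_history = history
    ),
    class = "atra_model"
  )
}

#' Scalar summary observables of a converged solve
#'
#' Computes, by trapezoidal quadrature on the solution grid, the scalar
#' observables reported for each simulated case: intraocular pressure, the
#' unconventional-outflow fraction, scleral and choriocapillaris fluid
#' fluxes, normalized albumin concentrations, mean atRA:SA concentrations,
#' and the integrated synthesis / vessel-leakage / scleral-consumption rates
#' of the atRA budget. Spatial means are thickness-weighted averages.
#'
#' The scleral consumption fraction is consumption divided by synthesis in
#' non-feeding cases and by synthesis plus (positive) blood leakage under
#' feeding, matching how production and consumption are compared in each
#' regime.
#'
#' @param fluid a converged [solve_fluid()] solution.
#' @param solute the matching [solve_solute()] solution.
#' @param params the [atra_params()] object used.
#' @return a one-row tibble.
#' @export
summarize_model <- function(fluid, solute, params) {
  x <- fluid$x
  i_if <- fluid$i_if
  N <- length(x)
  ch <- 1:i_if
  sc <- i_if:N
  a_ch <- capillary_density(x[ch], params)
  c2_B <- params$c_SA_blood_total - params$c3_B

  mean_sc <- function(v) trapz(x[sc], v[sc]) / (x[N] - x[i_if])
  mean_cs <- function(v) trapz(x, v) / (x[N] - x[1])

  u_CC <- trapz(x[ch], fluid$q[ch])
  u_S <- fluid$u_sclera[length(fluid$u_sclera)]
  part <- partition_outflow(fluid, params)

  synthesis <- params$A_S * params$k_prod * trapz(x[ch], a_ch)
  leak3 <- params$A_S * trapz(x[ch], params$beta * a_ch * (params$c3_B - solute$c3[ch]))
  leak2 <- params$A_S * trapz(x[ch], params$beta * a_ch * (c2_B - solute$c2[ch]))
  consumption <- params$A_S * trapz(x[sc], solute$r3[sc])
  denom <- synthesis + if (params$condition == "feeding") max(leak3, 0) else 0
  c3_orbit <- solute$c3[N]
  orbit_efflux <- params$A_S * (fluid$u_sclera[length(fluid$u_sclera)] * c3_orbit)

  tibble::tibble(
    species = params$species,
    condition = params$condition,
    iop_mmHg = fluid$iop / MMHG_PA,
    Qu = fluid$Q_u,
    Qu_over_Qprod = fluid$Q_u / params$Q_prod,
    u_S = u_S,
    u_CC = u_CC,
    uveovortex_fraction = part$uveovortex_fraction,
    uveoscleral_fraction = part$uveoscleral_fraction,
    drainage_ratio = part$drainage_ratio,
    c2S_over_c2B = mean_sc(solute$c2) / c2_B,
    mean_c2_CS = mean_cs(solute$c2),
    mean_c3_S_nM = mean_sc(solute$c3) / NM_MOLM3,
    mean_c3_CS_mM = mean_cs(solute$c3) / MM_MOLM3,
    c3_orbit_nM = c3_orbit / NM_MOLM3,
    SA_leak_rate = leak2,
    atRA_synthesis_rate = synthesis,
    atRA_blood_leak_rate = leak3,
    atRA_scleral_consumption_rate = consumption,
    atRA_orbit_efflux_rate = orbit_efflux,
    scleral_consumption_fraction = consumption / denom,
    max_r3_mM_s = max(solute$r3) / MM_MOLM3
  )
}

#' @export
print.atra_model <- function(x, ...) {
  cat(sprintf(
    "<atra_model> %s/%s: IOP %.2f mmHg, Qu/Qprod %.1f%%, <c3>_S %.3g nM (%d coupling iterations)\n",
    x$params$species, x$params$condition, x$summary$iop_mmHg,
    100 * x$summary$Qu_over_Qprod, x$summary$mean_c3_S_nM,
    x$coupling_iterations
  ))
  invisible(x)
}

#' Tidy profiles of a coupled solve
#'
#' @param x an `atra_model`.
#' @param ... unused.
#' @return a per-node tibble joining pressure, velocity, Starling source,
#'   concentrations and fluxes (interface node duplicated across layers for
#'   the velocity jump).
#' @export
tidy.atra_model <- function(x, ...) {
  fl <- tidy(x$fluid)
  so <- tidy(x$solute)
  # solute profile has a single interface row (choroid side); duplicate it
  so2 <- dplyr::bind_rows(
    so[seq_len(x$solute$i_if), ],
    dplyr::mutate(so[x$solute$i_if:nrow(so), ], layer = dplyr::if_else(
      dplyr::row_number() == 1L, "sclera", .data$layer
    ))
  )
  dplyr::bind_cols(fl, dplyr::select(so2, -"x", -"layer"))
}

#' One-row summary of a coupled solve
#'
#' @param x an `atra_model`.
#' @param ... unused.
#' @export
glance.atra_model <- function(x, ...) x$summary
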