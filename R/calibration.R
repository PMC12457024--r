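# Calibration of the four poorly known rate parameters (beta, Lp_star,
# k_prod, k_CYP_deg) against physiological targets, by bounded
# derivative-free minimization over log-transformed parameters.

#' Construct a calibration-target set
#'
#' Targets are the observables the uncertain parameters are fitted against:
#' intraocular pressure, the unconventional-outflow fraction, the normalized
#' mean scleral SA concentration, and the mean atRA:SA concentration over
#' choroid + sclera. For the mouse the atRA:SA target is available under
#' both control and feeding conditions (feeding changes only the blood
#' concentration `c3_B`), which is what makes the (`k_prod`, `k_CYP_deg`)
#' pair identifiable; for the human no atRA:SA target exists.
#'
#' @param iop_mmHg target intraocular pressure (mmHg).
#' @param qu_fraction target unconventional fraction of outflow (0-1).
#' @param c2s_ratio target mean scleral SA over blood SA (0-1).
#' @param c3cs_mM target mean atRA:SA over choroid + sclera (mM), control
#'   condition, or `NA` if unavailable.
#' @param c3cs_feeding_mM same under feeding, or `NA`.
#' @param weights named numeric weights for the five residuals (default 1).
#' @return a `calibration_targets` object (named list).
#' @export
#' @examples
#' mouse_targets <- calibration_targets(14.4, 0.20, 0.19, 0.75e-5, 0.68e-3)
calibration_targets <- function(iop_mmHg, qu_fraction, c2s_ratio,
                                c3cs_mM = NA_real_, c3cs_feeding_mM = NA_real_,
                                weights = NULL) {
  t <- list(
    iop_mmHg = iop_mmHg, qu_fraction = qu_fraction, c2s_ratio = c2s_ratio,
    c3cs_mM = c3cs_mM, c3cs_feeding_mM = c3cs_feeding_mM
  )
  vals <- unlist(t)
  if (any(!is.na(vals) & vals <= 0)) {
    rlang::abort("all calibration targets must be positive", class = "atraflux_validation_error")
  }
  w <- stats::setNames(rep(1, 5), names(t))
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(c(t, list(weights = w)), class = "calibration_targets")
}

#' Default target presets per species
#'
#' @param species `"mouse"` or `"human"`.
#' @return a [calibration_targets()] object holding the standard target
#'   values (mouse: IOP 14.4 mmHg, 20% unconventional, scleral SA ratio
#'   0.19, mean atRA:SA 0.75e-5 mM control / 0.68e-3 mM feeding; human:
#'   14.9 mmHg, 20%, 0.19, no atRA:SA target).
#' @export
default_targets <- function(species = c("mouse", "human")) {
  species <- rlang::arg_match(species)
  if (species == "mouse") {
    calibration_targets(14.4, 0.20, 0.19, 0.75e-5, 0.68e-3)
  } else {
    calibration_targets(14.9, 0.20, 0.19)
  }
}

.model_observables <- function(params, grid, include_atra = TRUE) {
  fit <- solve_steady_state(params, grid, include_atra = include_atra)
  s <- fit$summary
  c(
    iop_mmHg = s$iop_mmHg, qu_fraction = s$Qu_over_Qprod,
    c2s_ratio = s$c2S_over_c2B, c3cs_mM = s$mean_c3_CS_mM
  )
}

# weighted sum of squared relative deviations for the available targets
.objective <- function(obs_control, obs_feeding, targets) {
  resid <- c(
    iop_mmHg = (obs_control[["iop_mmHg"]] - targets$iop_mmHg) / targets$iop_mmHg,
    qu_fraction = (obs_control[["qu_fraction"]] - targets$qu_fraction) / targets$qu_fraction,
    c2s_ratio = (obs_control[["c2s_ratio"]] - targets$c2s_ratio) / targets$c2s_ratio,
    c3cs_mM = if (is.na(targets$c3cs_mM)) NA_real_ else {
      (obs_control[["c3cs_mM"]] - targets$c3cs_mM) / targets$c3cs_mM
    },
    c3cs_feeding_mM = if (is.na(targets$c3cs_feeding_mM) || is.null(obs_feeding)) NA_real_ else {
      (obs_feeding[["c3cs_mM"]] - targets$c3cs_feeding_mM) / targets$c3cs_feeding_mM
    }
  )
  list(residuals = resid, value = sum(targets$weights * resid^2, na.rm = TRUE))
}

.nm_minimize <- function(fn, x0, reltol = 1e-12, maxit = 500, restarts = 1) {
  best <- stats::optim(x0, fn,
    method = "Nelder-Mead",
    control = list(reltol = reltol, maxit = maxit)
  )
  for (r in seq_len(restarts)) {
    again <- stats::optim(best$par, fn,
      method = "Nelder-Mead",
      control = list(reltol = reltol, maxit = maxit)
    )
    if (again$value < best$value) best <- again
  }
  best
}

#' Fit the extremely uncertain parameters to calibration targets
#'
#' Minimizes a weighted sum of squared relative deviations between model
#' observables and targets over log-transformed free parameters, using
#' restarted Nelder-Mead within bounds `[1/bound_factor, bound_factor]`
#' times the starting values (enforced by quadratic penalty in log space).
#'
#' By default the fit runs in two stages, exploiting the one-way dependence
#' of atRA:SA on the fluid/SA problem at trace concentrations: first
#' (`Lp_star`, `beta`) against the fluid/SA targets with atRA transport
#' switched off, then (`k_prod`, `k_CYP_deg`) against the mean atRA:SA
#' targets. Parameters named in `free` but not separable this way are fitted
#' jointly in a single stage against all targets.
#'
#' @param params starting [atra_params()] (also supplies everything not
#'   fitted). Must be a control-condition set; the feeding target (if any)
#'   is evaluated by switching `c3_B` to the feeding preset value.
#' @param targets a [calibration_targets()] object.
#' @param free character subset of
#'   `c("Lp_star", "beta", "k_prod", "k_CYP_deg")`.
#' @param grid mesh used for the forward solves (default 200 + 200
#'   intervals: calibration accuracy is set by the optimizer, not by fine
#'   discretization).
#' @param bound_factor multiplicative half-width of the log-space box.
#' @param two_stage use the staged default (`TRUE`) or a joint fit.
#' @param reltol,maxit Nelder-Mead convergence controls.
#' @return an `atra_calibration` object: fitted parameter values, per-target
#'   residuals from a fresh forward solve, objective value, convergence
#'   diagnostics, and the updated `atra_params`.
#' @export
fit_uncertain_parameters <- function(params, targets,
                                     free = c("Lp_star", "beta", "k_prod", "k_CYP_deg"),
                                     grid = make_grid(params, 200, 200),
                                     bound_factor = 100,
                                     two_stage = TRUE,
                                     reltol = 1e-12, maxit = 500) {
  stopifnot(inherits(targets, "calibration_targets"))
  allowed <- c("Lp_star", "beta", "k_prod", "k_CYP_deg")
  free <- unique(free)
  if (length(free) && !all(free %in% allowed)) {
    rlang::abort(paste0("free parameters must be among: ", paste(allowed, collapse = ", ")),
      class = "atraflux_validation_error"
    )
  }
  if (params$condition != "control") {
    rlang::abort("calibration starts from a control-condition parameter set",
      class = "atraflux_precondition_error"
    )
  }
  need_feeding <- !is.na(targets$c3cs_feeding_mM) && params$species == "mouse"
  c3_B_feeding <- if (need_feeding) .preset_values("mouse", "feeding")$c3_B else NA_real_

  evals <- 0L
  eval_obs <- function(p, include_atra) {
    evals <<- evals + 1L
    ctrl <- .model_observables(p, grid, include_atra = include_atra)
    feed <- NULL
    if (include_atra && need_feeding && targets$weights[["c3cs_feeding_mM"]] > 0) {
      pf <- p
      pf$c3_B <- c3_B_feeding
      pf$condition <- "feeding"
      feed <- .model_observables(pf, grid, include_atra = TRUE)
    }
    list(control = ctrl, feeding = feed)
  }

  make_fn <- function(stage_free, include_atra, zero_weight = character(0)) {
    t2 <- targets
    t2$weights[zero_weight] <- 0
    x0 <- log(unlist(params[stage_free]))
    lo <- x0 - log(bound_factor)
    hi <- x0 + log(bound_factor)
    fn <- function(theta) {
      pen <- sum(pmax(theta - hi, 0)^2 + pmax(lo - theta, 0)^2)
      th <- pmin(pmax(theta, lo), hi)
      p <- params
      p[stage_free] <- as.list(exp(th))
      val <- tryCatch(
        {
          o <- eval_obs(p, include_atra)
          .objective(o$control, o$feeding, t2)$value
        },
        error = function(e) NA_real_
      )
      if (!is.finite(val)) {
        return(1e8 + pen)
      }
      val + 1e4 * pen
    }
    check0 <- fn(x0)
    if (!is.finite(check0) || check0 >= 1e8) {
      rlang::abort("objective is non-finite at the starting parameters",
        class = "atraflux_solver_error"
      )
    }
    list(fn = fn, x0 = x0, lo = lo, hi = hi)
  }

  fitted <- params
  diagnostics <- list()
  if (length(free)) {
    stage1 <- intersect(free, c("Lp_star", "beta"))
    stage2 <- intersect(free, c("k_prod", "k_CYP_deg"))
    if (two_stage && length(stage1) && length(stage2)) {
      f1 <- make_fn(stage1, include_atra = FALSE,
        zero_weight = c("c3cs_mM", "c3cs_feeding_mM"))
      o1 <- .nm_minimize(f1$fn, f1$x0, reltol, maxit)
      fitted[stage1] <- as.list(exp(pmin(pmax(o1$par, f1$lo), f1$hi)))
      params <- fitted
      f2 <- make_fn(stage2, include_atra = TRUE,
        zero_weight = c("iop_mmHg", "qu_fraction", "c2s_ratio"))
      o2 <- .nm_minimize(f2$fn, f2$x0, reltol, maxit)
      fitted[stage2] <- as.list(exp(pmin(pmax(o2$par, f2$lo), f2$hi)))
      diagnostics <- list(stage1 = o1, stage2 = o2)
    } else {
      # a pure fluid-stage fit with no atRA targets never needs the
      # (expensive) atRA transport solves
      inc <- length(stage2) > 0 ||
        (!is.na(targets$c3cs_mM) && targets$weights[["c3cs_mM"]] > 0) ||
        (need_feeding && targets$weights[["c3cs_feeding_mM"]] > 0)
      f <- make_fn(free, include_atra = inc)
      o <- .nm_minimize(f$fn, f$x0, reltol, maxit)
      fitted[free] <- as.list(exp(pmin(pmax(o$par, f$lo), f$hi)))
      diagnostics <- list(joint = o)
    }
  }
  fitted <- validate_params(fitted)

  # fresh forward solve for reproducible residuals
  obs <- eval_obs(fitted, include_atra = TRUE)
  final <- .objective(obs$control, obs$feeding, targets)
  # either the optimizer reported convergence or the targets are matched to
  # numerical precision (a simplex at a near-zero optimum can exhaust its
  # iteration budget without the reltol test firing)
  converged <- all(vapply(
    diagnostics,
    function(d) d$convergence == 0 || d$value < 1e-12, logical(1)
  ))
  structure(
    list(
      params = fitted,
      free = free,
      fitted_values = stats::setNames(
        vapply(free, function(f) fitted[[f]], numeric(1)), free
      ),
      residuals = final$residuals,
      objective = final$value,
      observables = obs$control,
      observables_feeding = obs$feeding,
      n_evaluations = evals,
      converged = if (length(free)) converged else TRUE,
      diagnostics = diagnostics,
      targets = targets
    ),
    class = "atra_calibration"
  )
}

#' @export
print.atra_calibration <- function(x, ...) {
  cat("<atra_calibration> objective ", format(x$objective, digits = 4),
    if (isTRUE(x$converged)) " (converged)" else " (NOT converged)", "\n",
    sep = ""
  )
  if (length(x$free)) print(x$fitted_values)
  invisible(x)
}

#' Tidy fitted calibration parameters
#'
#' @param x an `atra_calibration`.
#' @param ... unused.
#' @return tibble with one row per fitted parameter: `parameter`,
#'   `estimate`, `unit`.
#' @export
tidy.atra_calibration <- function(x, ...) {
  m <- .param_manifest()
  tibble::tibble(
    parameter = x$free,
    estimate = unname(x$fitted_values),
    unit = m$unit[match(x$free, m$symbol)]
  )
}

#' One-row calibration diagnostics
#'
#' @param x an `atra_calibration`.
#' @param ... unused.
#' @export
glance.atra_calibration <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_free = length(x$free),
    n_evaluations = x$n_evaluations,
    converged = x$converged,
    max_abs_rel_residual = max(abs(x$residuals), na.rm = TRUE)
  )
}
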