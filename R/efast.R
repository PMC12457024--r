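# Extended Fourier Amplitude Sensitivity Test (eFAST).
#
# Each parameter in turn is assigned the high driving frequency
# omega1 = floor((n - 1) / (2M)); the complementary parameters receive
# distinct low frequencies bounded by omega1/(2M) so that up to M harmonics
# do not interfere. The total-order index of the driven parameter is one
# minus the fraction of output variance found below omega1/2 (the
# complementary band), averaged over resampling curves with random phases.

#' Define an eFAST sensitivity design
#'
#' @param factors tibble/data.frame with columns `name`, `min`, `max`
#'   (absolute parameter bounds), one row per varied parameter.
#' @param n samples per search curve (per parameter). Must satisfy the
#'   Nyquist condition `n >= 4 * M * omega1 + 1`, which holds by
#'   construction for `omega1 = floor((n - 1)/(2M))`.
#' @param M number of interference-free harmonics (default 4).
#' @param n_resample number of resampling curves with independent random
#'   phases (default 5).
#' @param seed integer seed making the sampling deterministic.
#' @return an `efast_design` object.
#' @export
efast_design <- function(factors, n = 65, M = 4, n_resample = 5, seed = 1L) {
  factors <- tibble::as_tibble(factors)
  stopifnot(all(c("name", "min", "max") %in% names(factors)))
  if (any(factors$min >= factors$max)) {
    rlang::abort("each factor range must satisfy min < max",
      class = "atraflux_design_error"
    )
  }
  k <- nrow(factors)
  omega1 <- floor((n - 1) / (2 * M))
  if (omega1 < 1 || n < 4 * M * 1 + 1) {
    rlang::abort(sprintf("too few samples per curve (n = %d) for M = %d harmonics", n, M),
      class = "atraflux_design_error"
    )
  }
  if (k < 2) {
    rlang::abort("an eFAST design needs at least two factors (add a dummy factor)",
      class = "atraflux_design_error"
    )
  }
  structure(
    list(
      factors = factors, n = as.integer(n), M = as.integer(M),
      n_resample = as.integer(n_resample), seed = as.integer(seed),
      omega1 = as.integer(omega1)
    ),
    class = "efast_design"
  )
}

#' @export
print.efast_design <- function(x, ...) {
  cat(sprintf(
    "<efast_design> %d factors, n = %d per curve, M = %d, %d resampling curves (omega1 = %d)\n",
    nrow(x$factors), x$n, x$M, x$n_resample, x$omega1
  ))
  invisible(x)
}

#' Frequency assignment for the complementary parameter set
#'
#' Given `k` parameters with the driven one at frequency `omega1`, the
#' remaining `k - 1` receive frequencies no larger than `omega1/(2M)`:
#' evenly spread when that budget allows distinct values, cycled otherwise.
#'
#' @param k number of parameters.
#' @param omega1 driving frequency.
#' @param M interference factor.
#' @return integer vector of length `k - 1`.
#' @export
efast_frequencies <- function(k, omega1, M = 4) {
  m <- max(1L, floor(omega1 / (2 * M)))
  if (m >= k - 1) {
    floor(seq(1, m, length.out = k - 1))
  } else {
    ((seq_len(k - 1) - 1L) %% m) + 1L
  }
}

# sample matrices for one (driven parameter, resampling curve) pair
.efast_curve <- function(design, i_driven, phases) {
  k <- nrow(design$factors)
  n <- design$n
  s <- 2 * pi * (0:(n - 1)) / n
  omega <- numeric(k)
  omega[i_driven] <- design$omega1
  omega[-i_driven] <- efast_frequencies(k, design$omega1, design$M)
  X <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    g <- 0.5 + asin(sin(omega[j] * s + phases[j])) / pi
    X[, j] <- design$factors$min[j] + g * (design$factors$max[j] - design$factors$min[j])
  }
  colnames(X) <- design$factors$name
  X
}

#' Generate the full eFAST sample matrix
#'
#' @param design an [efast_design()].
#' @return tibble with one row per model evaluation and columns
#'   `.driven` (which parameter owns the high frequency), `.curve`
#'   (resampling index), `.s_index` (position along the curve), plus one
#'   column per factor. Deterministic given the design seed.
#' @export
efast_sample <- function(design) {
  stopifnot(inherits(design, "efast_design"))
  k <- nrow(design$factors)
  out <- vector("list", k * design$n_resample)
  idx <- 1L
  rs <- .efast_rng(design$seed)
  for (i in seq_len(k)) {
    for (r in seq_len(design$n_resample)) {
      phases <- rs(k) * 2 * pi
      X <- .efast_curve(design, i, phases)
      out[[idx]] <- dplyr::bind_cols(
        tibble::tibble(
          .driven = design$factors$name[i], .curve = r,
          .s_index = seq_len(design$n)
        ),
        tibble::as_tibble(X)
      )
      idx <- idx + 1L
    }
  }
  dplyr::bind_rows(out)
}

# local deterministic uniform stream that leaves the global RNG untouched
.efast_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    u
  }
}

#' Total-order eFAST sensitivity indices
#'
#' Evaluates `model` along every search curve of the design and computes,
#' for each (parameter, output) pair, the total sensitivity index
#' `S_T = 1 - V_complementary / V_total`, where the complementary variance
#' is the spectral power below `omega1 / 2`. Effect directions come from the
#' sign of the Spearman rank correlation between the parameter's samples and
#' the output (`|rho| > 0.1`, otherwise `"indeterminate"`).
#'
#' @param model function mapping a named numeric parameter vector (one row
#'   of the sample) to a named numeric vector of outputs. Evaluations that
#'   error or return non-finite values are imputed from the nearest
#'   successful sample on the same curve; if more than `fail_budget` of all
#'   evaluations fail, the analysis aborts.
#' @param design an [efast_design()].
#' @param fail_budget maximum tolerated fraction of failed evaluations.
#' @return an `efast_result`: tibble with columns `parameter`, `output`,
#'   `S_T`, `S_T_se` (standard error over resampling curves), `direction`
#'   (`"+"`, `"-"` or `"indeterminate"`), `rho`, and attributes holding the
#'   design and failure count.
#' @export
efast_total_index <- function(model, design, fail_budget = 0.05) {
  samples <- efast_sample(design)
  factor_names <- design$factors$name
  X <- as.matrix(samples[factor_names])
  n_eval <- nrow(X)

  first <- NULL
  ys <- vector("list", n_eval)
  failed <- logical(n_eval)
  for (i in seq_len(n_eval)) {
    y <- tryCatch(model(X[i, ]), error = function(e) NULL)
    if (is.null(y) || any(!is.finite(y))) {
      failed[i] <- TRUE
      ys[i] <- list(NULL)
    } else {
      ys[[i]] <- y
      if (is.null(first)) first <- y
    }
  }
  if (mean(failed) > fail_budget) {
    rlang::abort(
      sprintf(
        "%.1f%% of model evaluations failed (budget %.1f%%)",
        100 * mean(failed), 100 * fail_budget
      ),
      class = "atraflux_solver_error"
    )
  }
  if (is.null(first)) {
    rlang::abort("all model evaluations failed", class = "atraflux_solver_error")
  }
  out_names <- names(first)
  if (is.null(out_names)) out_names <- paste0("y", seq_along(first))
  Y <- matrix(NA_real_, n_eval, length(first), dimnames = list(NULL, out_names))
  for (i in seq_len(n_eval)) if (!failed[i]) Y[i, ] <- ys[[i]]
  # impute failures from the nearest successful sample on the same curve
  if (any(failed)) {
    key <- paste(samples$.driven, samples$.curve)
    for (i in which(failed)) {
      same <- which(key == key[i] & !failed)
      if (!length(same)) {
        rlang::abort("an entire eFAST curve failed to evaluate", class = "atraflux_solver_error")
      }
      Y[i, ] <- Y[same[which.min(abs(samples$.s_index[same] - samples$.s_index[i]))], ]
    }
  }

  spectral_st <- function(y, omega1) {
    n <- length(y)
    co <- Mod(stats::fft(y))^2 / n^2
    half <- (n - 1) %/% 2
    lam <- 2 * co[2:(half + 1)] # one-sided spectrum, frequencies 1..half
    V <- sum(lam)
    Vc <- sum(lam[seq_len(floor(omega1 / 2))])
    if (V <= 0) return(0)
    1 - Vc / V
  }

  res <- list()
  for (oo in out_names) {
    for (pn in factor_names) {
      sel <- samples$.driven == pn
      st_curves <- vapply(seq_len(design$n_resample), function(r) {
        rows <- sel & samples$.curve == r
        spectral_st(Y[rows, oo], design$omega1)
      }, numeric(1))
      rho <- suppressWarnings(stats::cor(X[sel, pn], Y[sel, oo], method = "spearman"))
      direction <- if (!is.finite(rho) || abs(rho) <= 0.1) {
        "indeterminate"
      } else if (rho > 0) "+" else "-"
      res[[length(res) + 1L]] <- tibble::tibble(
        parameter = pn, output = oo,
        S_T = mean(st_curves),
        S_T_se = if (design$n_resample > 1) {
          stats::sd(st_curves) / sqrt(design$n_resample)
        } else {
          NA_real_
        },
        direction = direction, rho = rho
      )
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "design") <- design
  attr(out, "n_failed") <- sum(failed)
  class(out) <- c("efast_result", class(out))
  out
}

#' Factor ranges for the standard sensitivity studies
#'
#' Builds the factor table for the two analyses run on the transport model:
#' the fluid/SA set (`K_S`, `Lp_star`, `beta`, `u_RPE`, `dP_blood`,
#' `dP_SCS`) and the atRA set, which adds `k_prod`, `k_CYP_deg`, `Ind_C50`
#' and `c3_B`. Ranges: `K_S`, `u_RPE`, `Ind_C50`, `c3_B` vary over
#' 0.5-1.5 times their reference value; `dP_blood` over 3-7 mmHg and
#' `dP_SCS` over 0-2 mmHg; the four extremely uncertain rates over 1/3-3
#' times reference. Optionally appends an inert `dummy` factor whose index
#' estimates the noise floor.
#'
#' @param params reference [atra_params()].
#' @param set `"fluid"` or `"atra"`.
#' @param dummy append an inert factor (default `TRUE`).
#' @return tibble with columns `name`, `min`, `max`.
#' @export
efast_factors <- function(params, set = c("fluid", "atra"), dummy = TRUE) {
  set <- rlang::arg_match(set)
  half <- function(sym) {
    tibble::tibble(name = sym, min = 0.5 * params[[sym]], max = 1.5 * params[[sym]])
  }
  third <- function(sym) {
    tibble::tibble(name = sym, min = params[[sym]] / 3, max = 3 * params[[sym]])
  }
  f <- dplyr::bind_rows(
    half("K_S"),
    third("Lp_star"),
    third("beta"),
    half("u_RPE"),
    tibble::tibble(name = "dP_blood", min = 3 * MMHG_PA, max = 7 * MMHG_PA),
    tibble::tibble(name = "dP_SCS", min = 0, max = 2 * MMHG_PA)
  )
  if (set == "atra") {
    f <- dplyr::bind_rows(f, third("k_prod"), third("k_CYP_deg"),
      half("Ind_C50"), half("c3_B"))
  }
  # dP_SCS lower bound 0 is a closed range endpoint, not a degenerate range
  if (dummy) f <- dplyr::bind_rows(f, tibble::tibble(name = "dummy", min = 0, max = 1))
  f
}

#' Model wrapper for sensitivity analysis of the transport model
#'
#' Returns a closure suitable for [efast_total_index()]: it receives a named
#' vector of parameter values (a subset of the parameter-set fields, plus
#' optionally an ignored `dummy`), solves the coupled steady state on a
#' fixed mesh, and returns the requested scalar outputs.
#'
#' @param params base [atra_params()].
#' @param outputs character subset of `c("iop_mmHg", "u_CC", "u_S",
#'   "mean_c2_CS", "mean_c3_S_nM", "c3_orbit_nM")`.
#' @param grid_n intervals per layer of the solver mesh (coarser than the
#'   default production mesh; sensitivity rankings are insensitive to this).
#' @param include_atra solve atRA transport (needed for the atRA outputs).
#' @param check forwarded to [solve_steady_state()]; defaults to `FALSE`
#'   because extreme corners of the sensitivity ranges can drive the eye
#'   into unphysical regimes (reversed scleral flow) whose converged,
#'   clamped states still carry variance information.
#' @return function mapping named parameter vector to named output vector.
#' @export
sensitivity_model <- function(params,
                              outputs = c("iop_mmHg", "u_CC", "u_S", "mean_c2_CS"),
                              grid_n = 100, include_atra = FALSE, check = FALSE) {
  outputs <- match.arg(outputs,
    c("iop_mmHg", "u_CC", "u_S", "mean_c2_CS", "mean_c3_S_nM", "c3_orbit_nM"),
    several.ok = TRUE
  )
  grid <- make_grid(params, grid_n, grid_n)
  function(x) {
    p <- params
    for (nm in setdiff(names(x), "dummy")) p[[nm]] <- unname(x[[nm]])
    fit <- solve_steady_state(p, grid, include_atra = include_atra, check = check)
    unlist(fit$summary[outputs])
  }
}

#' Plot eFAST total sensitivity indices
#'
#' Bar chart of total-order indices per parameter, faceted by model output,
#' with effect directions annotated.
#'
#' @param result an [efast_total_index()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(result, ...) {
  stopifnot(inherits(result, "efast_result"))
  ggplot2::ggplot(
    result,
    ggplot2::aes(x = .data$parameter, y = .data$S_T, fill = .data$direction)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(
      x = NULL, y = expression(S[T]),
      title = "eFAST total sensitivity indices"
    ) +
    ggplot2::theme_minimal()
}
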