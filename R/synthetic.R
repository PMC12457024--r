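# Synthetic-data generators: serum atRA time courses with the measured
# control mean/SD and feeding rise-to-plateau shape, and noisy calibration
# targets from known ground-truth parameters for recovery testing.
#
# All generators are pure functions of (seed, arguments) and leave the
# global RNG state untouched.

# serum curve constants (pmol/ml): control mean/SD; fed plateau and the
# Hill-rise shape pinned to the measured 4.1 nmol/ml at 30 min and
# 11.67 nmol/ml at 90 min
.SERUM_CONTROL_MEAN <- 1.25
.SERUM_CONTROL_SD <- 0.54
.SERUM_FED_PLATEAU <- 12e3
.SERUM_FED_T50 <- 35.60121
.SERUM_FED_HILL <- 3.842998

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Noise-free fed-cohort serum atRA curve
#'
#' Hill-type sigmoid rise to plateau,
#' `C(t) = C_plateau * t^h / (t50^h + t^h)` (pmol/ml), with shape constants
#' pinned to the measured serum concentrations 4.1 nmol/ml at 30 min and
#' 11.67 nmol/ml at 90 min after feeding, plateauing near 12 nmol/ml by
#' 120 min.
#'
#' @param time_min minutes after feeding (nonnegative).
#' @return concentration in pmol/ml.
#' @export
serum_fed_curve <- function(time_min) {
  if (any(time_min < 0)) {
    rlang::abort("times must be nonnegative", class = "atraflux_domain_error")
  }
  th <- time_min^.SERUM_FED_HILL
  .SERUM_FED_PLATEAU * th / (.SERUM_FED_T50^.SERUM_FED_HILL + th)
}

#' Generate a synthetic serum atRA time course
#'
#' Control animals draw from a positive-truncated normal with mean 1.25 and
#' SD 0.54 pmol/ml (feeding times are irrelevant for controls but retained
#' in the output for a tidy layout). Fed animals follow [serum_fed_curve()]
#' with multiplicative log-normal noise of coefficient of variation
#' `noise_cv`.
#'
#' @param seed integer seed; identical calls are bit-identical.
#' @param cohort `"control"` or `"fed"`.
#' @param n_animals number of animals (>= 1).
#' @param times sampling times in minutes after feeding.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise for the fed cohort (default 0.2; 0 gives the exact
#'   curve).
#' @return tibble with columns `animal_id`, `cohort`, `time_min`,
#'   `conc_pmol_per_ml`.
#' @export
generate_serum_timecourse <- function(seed, cohort = c("control", "fed"),
                                      n_animals = 8,
                                      times = c(30, 60, 90, 120),
                                      noise_cv = 0.2) {
  cohort <- rlang::arg_match(cohort)
  stopifnot(n_animals >= 1)
  if (any(times < 0)) {
    rlang::abort("times must be nonnegative", class = "atraflux_domain_error")
  }
  grid <- tidyr::expand_grid(animal_id = seq_len(n_animals), time_min = as.numeric(times))
  .with_seed(seed, {
    if (cohort == "control") {
      # positive-truncated normal by rejection
      draw <- function(n) {
        out <- numeric(0)
        while (length(out) < n) {
          z <- stats::rnorm(n, .SERUM_CONTROL_MEAN, .SERUM_CONTROL_SD)
          out <- c(out, z[z > 0])
        }
        out[seq_len(n)]
      }
      conc <- draw(nrow(grid))
    } else {
      mu <- serum_fed_curve(grid$time_min)
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        conc <- mu * stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        conc <- mu
      }
    }
    tibble::tibble(
      animal_id = grid$animal_id, cohort = cohort,
      time_min = grid$time_min, conc_pmol_per_ml = conc
    )
  })
}

#' Reduce serum measurements to the model's blood atRA:SA concentration
#'
#' Arithmetic mean of the measured concentrations inside a time window,
#' converted to SI (1 pmol/ml = 1e-6 mol/m^3). For control cohorts the
#' window may span all times.
#'
#' @param measurements tibble from [generate_serum_timecourse()] (or a
#'   matching CSV read back with [read_serum_csv()]).
#' @param window length-2 numeric time interval (min), inclusive.
#' @return blood atRA:SA concentration `c3_B` in mol m^-3.
#' @export
serum_to_model_input <- function(measurements, window = c(0, Inf)) {
  sel <- measurements$time_min >= window[1] & measurements$time_min <= window[2]
  if (!any(sel)) {
    rlang::abort("no measurements fall inside the requested window",
      class = "atraflux_domain_error"
    )
  }
  mean(measurements$conc_pmol_per_ml[sel]) * PMOLML_MOLM3
}

#' Read / write serum measurement CSV files
#'
#' Plain CSV with columns `animal_id`, `cohort`, `time_min`,
#' `conc_pmol_per_ml`.
#'
#' @param measurements tibble of serum measurements.
#' @param path file path.
#' @export
write_serum_csv <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' @rdname write_serum_csv
#' @export
read_serum_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      animal_id = readr::col_integer(), cohort = readr::col_character(),
      time_min = readr::col_double(), conc_pmol_per_ml = readr::col_double()
    )
  )
}

#' Generate (possibly noisy) calibration targets from known parameters
#'
#' Runs the coupled forward model at `true_params`, extracts the four
#' calibration observables (plus the feeding atRA:SA mean for the mouse),
#' and perturbs each multiplicatively with log-normal noise of coefficient
#' of variation `noise_cv`. With `noise_cv = 0` the targets equal the
#' forward-model outputs exactly, enabling parameter-recovery testing.
#'
#' @param true_params ground-truth [atra_params()] (control condition).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param grid mesh for the forward solves.
#' @return a [calibration_targets()] object.
#' @export
generate_calibration_targets <- function(true_params, noise_cv = 0, seed = 1L,
                                         grid = make_grid(true_params, 200, 200)) {
  fit <- solve_steady_state(true_params, grid)
  s <- fit$summary
  vals <- c(
    iop = s$iop_mmHg, qu = s$Qu_over_Qprod, c2 = s$c2S_over_c2B,
    c3 = s$mean_c3_CS_mM
  )
  c3_feed <- NA_real_
  if (true_params$species == "mouse") {
    pf <- true_params
    pf$c3_B <- .preset_values("mouse", "feeding")$c3_B
    pf$condition <- "feeding"
    c3_feed <- solve_steady_state(pf, grid)$summary$mean_c3_CS_mM
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- .with_seed(seed, stats::rlnorm(5, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    vals <- vals * noise[1:4]
    if (!is.na(c3_feed)) c3_feed <- c3_feed * noise[5]
  }
  calibration_targets(
    iop_mmHg = vals[["iop"]], qu_fraction = vals[["qu"]],
    c2s_ratio = vals[["c2"]], c3cs_mM = vals[["c3"]],
    c3cs_feeding_mM = c3_feed
  )
}
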