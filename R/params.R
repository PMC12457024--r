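# Parameter handling: presets, validation, unit conversion, file round-trip.
#
# All parameters are stored in strict SI units (Pa, m, s, mol m^-3); the
# pressure/flow entries that are conventionally quoted in mmHg and ul/min are
# converted once, at construction or file-reading time.

#' Unit conversion constants
#'
#' Pressure and flow-rate conversions applied at the I/O boundary. All
#' internal computation is in SI units.
#'
#' @format `MMHG_PA` is Pa per mmHg; `ULMIN_M3S` is m^3 s^-1 per ul min^-1;
#'   `MM_MOLM3` is mol m^-3 per mM (identity); `NM_MOLM3` is mol m^-3 per nM;
#'   `PMOLML_MOLM3` is mol m^-3 per pmol ml^-1.
#' @name unit-constants
#' @keywords internal
NULL

MMHG_PA <- 133.322
ULMIN_M3S <- 1e-9 / 60
MM_MOLM3 <- 1
NM_MOLM3 <- 1e-6
PMOLML_MOLM3 <- 1e-6

# field name -> c(unit, category) for every entry of a parameter set
.param_manifest <- function() {
  tribble_chr <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(symbol = m[, 1], unit = m[, 2], category = m[, 3])
  }
  tribble_chr(
    "L_C", "m", "well-known",
    "L_S", "m", "well-known",
    "alpha", "1", "somewhat-known",
    "Gamma", "1", "well-known",
    "R_gas", "J mol-1 K-1", "well-known",
    "T_abs", "K", "well-known",
    "mu", "Pa s", "well-known",
    "u_RPE", "m s-1", "somewhat-known",
    "p_orbit", "Pa", "well-known",
    "dP_blood", "Pa", "somewhat-known",
    "dP_SCS", "Pa", "somewhat-known",
    "EVP", "Pa", "well-known",
    "Q_prod", "m3 s-1", "well-known",
    "C_fac", "m3 s-1 Pa-1", "well-known",
    "Lp_star", "s-1 Pa-1", "extremely-uncertain",
    "K_S", "m2", "somewhat-known",
    "K_C", "m2", "somewhat-known",
    "D2_S", "m2 s-1", "well-known",
    "D3_S", "m2 s-1", "well-known",
    "D2_C", "m2 s-1", "well-known",
    "D3_C", "m2 s-1", "well-known",
    "beta", "s-1", "extremely-uncertain",
    "c_SA_blood_total", "mol m-3", "well-known",
    "c3_B", "mol m-3", "well-known",
    "sigma", "1", "well-known",
    "k_prod", "mol m-3 s-1", "extremely-uncertain",
    "k_CYP_deg", "s-1", "extremely-uncertain",
    "Ind_max", "1", "somewhat-known",
    "Ind_C50", "mol m-3", "somewhat-known",
    "f_u_inc", "1", "somewhat-known",
    "A_S", "m2", "well-known",
    "Ka", "M-1", "somewhat-known"
  )
}

#' Units and uncertainty category of every model parameter
#'
#' @return A tibble with columns `symbol`, `unit` and `category`
#'   (well-known / somewhat-known / extremely-uncertain). Units are the
#'   internal SI units, not the mixed conventional units of the physiology
#'   literature.
#' @export
#' @examples
#' parameter_units()
parameter_units <- function() .param_manifest()

.preset_values <- function(species, condition) {
  base_common <- list(
    Gamma = 100,
    R_gas = 8.314,
    T_abs = 310,
    mu = 0.7e-3,
    sigma = 1,
    Ind_max = 33,
    Ind_C50 = 90 * NM_MOLM3,
    f_u_inc = 0.4,
    Ka = 2.3e6
  )
  mouse <- list(
    L_S = 70e-6, L_C = 30e-6, alpha = 0.3,
    u_RPE = 23e-8,
    p_orbit = 3 * MMHG_PA, dP_blood = 5 * MMHG_PA, dP_SCS = 1 * MMHG_PA,
    EVP = 7.5 * MMHG_PA,
    Q_prod = 48e-3 * ULMIN_M3S,
    C_fac = 5.9e-3 * ULMIN_M3S / MMHG_PA,
    Lp_star = 3.56e-5,
    K_S = 6.4e-18, K_C = 100 * 6.4e-18,
    D2_S = 9.6e-12, D3_S = 9.6e-12, D2_C = 8.75e-11, D3_C = 8.75e-11,
    beta = 1.37e-3,
    c_SA_blood_total = 0.41,
    c3_B = 1.25 * PMOLML_MOLM3,
    k_prod = 7.8e-8,
    k_CYP_deg = 3.5e-4,
    A_S = 3.2e-5
  )
  human <- list(
    L_S = 670e-6, L_C = 268e-6, alpha = 0.034,
    u_RPE = 3e-8,
    p_orbit = 3 * MMHG_PA, dP_blood = 5 * MMHG_PA, dP_SCS = 1 * MMHG_PA,
    EVP = 7.1 * MMHG_PA,
    Q_prod = 2.53 * ULMIN_M3S,
    C_fac = 0.26 * ULMIN_M3S / MMHG_PA,
    Lp_star = 1.83e-7,
    K_S = 1.33e-18, K_C = 100 * 1.33e-18,
    D2_S = 9.6e-12, D3_S = 9.6e-12, D2_C = 8.75e-11, D3_C = 8.75e-11,
    beta = 3.4e-6,
    c_SA_blood_total = 0.68,
    c3_B = 2.5e-6,
    k_prod = 1.01e-8,
    k_CYP_deg = 4.56e-5,
    A_S = 1.49e-3
  )
  p <- c(base_common, switch(species, mouse = mouse, human = human))
  if (species == "mouse" && condition == "feeding") {
    # serum measurement 90 min after feeding: 11.67 nmol/ml
    p$c3_B <- 11.67e3 * PMOLML_MOLM3
  }
  p
}

#' Build a validated parameter set
#'
#' Constructs the full parameter set for one of the three simulated cases
#' (mouse control, mouse with atRA feeding, human control), optionally with
#' individual fields overridden. All values are held in SI units; the
#' conventional mmHg / ul min^-1 / mM entries of the physiology literature
#' are converted internally.
#'
#' The mouse feeding preset differs from mouse control only in the blood
#' atRA:SA concentration `c3_B`.
#'
#' @param species `"mouse"` or `"human"`.
#' @param condition `"control"` or `"feeding"`. Feeding is only simulated in
#'   the mouse.
#' @param ... named overrides of individual parameter fields, in SI units.
#' @return An object of class `atra_params`: a named list of parameter values
#'   with `species` and `condition` tags.
#' @export
#' @examples
#' p <- atra_params("human")
#' p$L_S # scleral thickness, m
atra_params <- function(species = c("mouse", "human"),
                        condition = c("control", "feeding"), ...) {
  species <- rlang::arg_match(species)
  condition <- rlang::arg_match(condition)
  if (species == "human" && condition == "feeding") {
    rlang::abort("the human feeding scenario is not modelled", class = "atraflux_lookup_error")
  }
  p <- .preset_values(species, condition)
  dots <- rlang::list2(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      rlang::abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")),
        class = "atraflux_lookup_error"
      )
    }
    p[names(dots)] <- dots
  }
  p$species <- species
  p$condition <- condition
  validate_params(new_atra_params(p))
}

new_atra_params <- function(x) structure(x, class = "atra_params")

#' Validate physical admissibility of a parameter set
#'
#' Checks that every field is present, that all lengths, areas,
#' permeabilities and diffusivities are strictly positive (rate-like
#' parameters may be exactly zero, giving useful degenerate limits),
#' `0 < alpha < 1`,
#' `0 <= sigma <= 1`, `0 < f_u_inc <= 1`, `Gamma >> 1`, and
#' `c3_B <= c_SA_blood_total`.
#'
#' @param params an `atra_params` object (or plain named list).
#' @return the validated `atra_params` object, invisibly usable in pipes.
#' @export
validate_params <- function(params) {
  need <- .param_manifest()$symbol
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    rlang::abort(
      paste0("parameter set is missing field(s): ", paste(missing, collapse = ", ")),
      class = "atraflux_validation_error"
    )
  }
  strictly_pos <- c(
    "L_C", "L_S", "R_gas", "T_abs", "mu", "Q_prod", "C_fac",
    "K_S", "K_C", "D2_S", "D3_S", "D2_C", "D3_C",
    "c_SA_blood_total", "Ind_max", "Ind_C50",
    "A_S", "Gamma"
  )
  # rate-like parameters admit exact zero (useful degenerate limits:
  # no filtration, no vessel leakage, no pumping, no synthesis/degradation)
  nonneg <- c("Lp_star", "beta", "u_RPE", "k_prod", "k_CYP_deg", "c3_B")
  for (f in need) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(paste0("parameter '", f, "' must be a finite scalar"),
        class = "atraflux_validation_error"
      )
    }
  }
  for (f in strictly_pos) {
    if (params[[f]] <= 0) {
      rlang::abort(paste0("parameter '", f, "' must be strictly positive"),
        class = "atraflux_validation_error"
      )
    }
  }
  for (f in nonneg) {
    if (params[[f]] < 0) {
      rlang::abort(paste0("parameter '", f, "' must be nonnegative"),
        class = "atraflux_validation_error"
      )
    }
  }
  if (params$alpha <= 0 || params$alpha >= 1) {
    rlang::abort("'alpha' must lie strictly between 0 and 1", class = "atraflux_validation_error")
  }
  if (params$sigma < 0 || params$sigma > 1) {
    rlang::abort("'sigma' must lie in [0, 1]", class = "atraflux_validation_error")
  }
  if (params$f_u_inc <= 0 || params$f_u_inc > 1) {
    rlang::abort("'f_u_inc' must lie in (0, 1]", class = "atraflux_validation_error")
  }
  if (params$Gamma < 10) {
    rlang::abort("'Gamma' must be much larger than 1 (>= 10)", class = "atraflux_validation_error")
  }
  if (params$c3_B > params$c_SA_blood_total) {
    rlang::abort("'c3_B' cannot exceed the total blood albumin 'c_SA_blood_total'",
      class = "atraflux_validation_error"
    )
  }
  if (params$Ka < 0) {
    rlang::abort("'Ka' must be nonnegative", class = "atraflux_validation_error")
  }
  params
}

#' Load a parameter set from a preset name or a parameter file
#'
#' @param source either a preset string of the form `"<species>-<condition>"`
#'   (one of `"mouse-control"`, `"mouse-feeding"`, `"human-control"`) or a
#'   path to a YAML/JSON parameter file written by [write_params()].
#' @param species,condition used when `source` is missing, as an alternative
#'   way of naming the preset.
#' @return a validated [atra_params()] object.
#' @export
#' @examples
#' load_parameters("mouse-feeding")$c3_B
load_parameters <- function(source = NULL, species = NULL, condition = "control") {
  if (is.null(source)) {
    return(atra_params(species = species, condition = condition))
  }
  presets <- c("mouse-control", "mouse-feeding", "human-control")
  if (source %in% presets) {
    parts <- strsplit(source, "-", fixed = TRUE)[[1]]
    return(atra_params(species = parts[1], condition = parts[2]))
  }
  if (!file.exists(source)) {
    rlang::abort(paste0("'", source, "' is neither a known preset (",
      paste(presets, collapse = ", "), ") nor a readable file"),
      class = "atraflux_lookup_error"
    )
  }
  read_params(source)
}

#' Read / write parameter files
#'
#' Parameter files are YAML (default) or JSON, keyed by the internal symbol
#' names and holding SI values; the round trip through
#' `write_params()`/`read_params()` preserves every field bit-exactly (values
#' are serialized at full double precision).
#'
#' @param params an `atra_params` object.
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @return `read_params()` returns a validated `atra_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "atra_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 17)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("parameter file not found: ", path), class = "atraflux_lookup_error")
  }
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  x <- as.list(x)
  numeric_fields <- .param_manifest()$symbol
  for (f in intersect(names(x), numeric_fields)) x[[f]] <- as.numeric(x[[f]])
  validate_params(new_atra_params(x))
}

#' @export
print.atra_params <- function(x, ...) {
  cat("<atra_params> ", x$species, "/", x$condition, "\n", sep = "")
  print(tidy.atra_params(x), n = Inf)
  invisible(x)
}

#' Tidy a parameter set into a symbol/value/unit/category tibble
#'
#' @param x an `atra_params` object.
#' @param ... unused.
#' @export
tidy.atra_params <- function(x, ...) {
  m <- .param_manifest()
  m$value <- unname(vapply(m$symbol, function(s) as.numeric(x[[s]]), numeric(1)))
  dplyr::relocate(m, "value", .after = "symbol")
}

#' Smoothed step profile of filtering-capillary density across the choroid
#'
#' The choriocapillaris occupies the inner fraction `alpha` of the choroidal
#' thickness; the capillary surface density is modelled as the smoothed step
#' `a(x) = (1/alpha) * (1 - 1/(1 + exp(-Gamma*(x/L_C - alpha))))`, normalized
#' so that its integral over the choroid is approximately `L_C`. At
#' `x = alpha*L_C` it equals `1/(2*alpha)` exactly.
#'
#' @param x positions in the choroid (m), `0 <= x <= L_C`.
#' @param params an [atra_params()] object.
#' @return dimensionless density values, same length as `x`.
#' @export
#' @examples
#' p <- atra_params("mouse")
#' capillary_density(p$alpha * p$L_C, p) * 2 * p$alpha # == 1
capillary_density <- function(x, params) {
  if (any(x < -1e-12 * params$L_C | x > params$L_C * (1 + 1e-12))) {
    rlang::abort("position x must lie within the choroid [0, L_C]",
      class = "atraflux_domain_error"
    )
  }
  # logistic written via plogis for numerical stability at large Gamma
  (1 / params$alpha) * stats::plogis(-params$Gamma * (x / params$L_C - params$alpha))
}
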