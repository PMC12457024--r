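test_that("presets hold the tabulated values in coherent SI units", {
  mc <- atra_params("mouse", "control")
  hc <- atra_params("human", "control")
  mf <- atra_params("mouse", "feeding")

  expect_equal(mc$L_S, 70e-6)
  expect_equal(hc$L_S, 670e-6)
  expect_equal(hc$c3_B, 2.5e-6) # 2.5 nM
  expect_equal(mc$c3_B, 1.25e-6) # 1.25 pmol/ml
  expect_equal(mf$c3_B, 1.167e-2) # 11.67 nmol/ml
  # mmHg and ul/min entries converted at the boundary
  expect_equal(hc$EVP, 7.1 * 133.322)
  expect_equal(hc$Q_prod, 2.53e-9 / 60)

  # feeding differs from control only in the blood atRA:SA concentration
  mc2 <- mc
  mc2$c3_B <- mf$c3_B
  mc2$condition <- "feeding"
  expect_identical(unclass(mc2), unclass(mf))
})

test_that("invalid parameter sets are rejected with the offending field named", {
  expect_error(atra_params("human", "feeding"), class = "atraflux_lookup_error")
  expect_error(atra_params("mouse", L_S = -1), regexp = "L_S")
  expect_error(atra_params("mouse", alpha = 1.2), regexp = "alpha")
  expect_error(atra_params("mouse", nonsense = 1), class = "atraflux_lookup_error")
  expect_error(
    atra_params("mouse", c3_B = 1), # exceeds total blood albumin
    class = "atraflux_validation_error"
  )

  # a file lacking K_S names the missing field
  p <- atra_params("mouse")
  f <- withr::local_tempfile(fileext = ".yaml")
  x <- unclass(p)
  x$K_S <- NULL
  yaml::write_yaml(x, f)
  expect_error(read_params(f), regexp = "K_S")
})

test_that("parameter files round-trip bit-exactly through YAML and JSON", {
  p <- atra_params("human")
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_params(p, f)
    q <- read_params(f)
    for (nm in parameter_units()$symbol) expect_identical(q[[nm]], p[[nm]], label = nm)
    expect_identical(q$species, p$species)
  }
})

test_that("preset lookup accepts names and falls through to files", {
  expect_identical(
    unclass(load_parameters("mouse-feeding")),
    unclass(atra_params("mouse", "feeding"))
  )
  expect_error(load_parameters("rabbit-control"), class = "atraflux_lookup_error")
  f <- withr::local_tempfile(fileext = ".json")
  write_params(atra_params("human"), f)
  expect_identical(unclass(load_parameters(f)), unclass(atra_params("human")))
})

test_that("capillary density is a smoothed step with the stated properties", {
  for (sp in c("mouse", "human")) {
    p <- atra_params(sp)
    # half height exactly at the choriocapillaris edge
    expect_equal(capillary_density(p$alpha * p$L_C, p), 1 / (2 * p$alpha))
    x <- seq(0, p$L_C, length.out = 20001)
    a <- capillary_density(x, p)
    expect_true(all(a >= 0 & a <= 1 / p$alpha))
    expect_true(all(diff(a) <= 1e-12)) # monotonically nonincreasing
    # integral approximates the choroidal thickness to better than 1%
    int <- sum(diff(x) * (a[-1] + a[-length(a)]) / 2)
    expect_rel(int, p$L_C, 0.01)
  }
  # the step has decayed to numerically nothing at the interface (mouse alpha)
  pm <- atra_params("mouse")
  expect_lt(capillary_density(pm$L_C, pm), 1e-12 / pm$alpha)
  expect_error(capillary_density(-1e-6, pm), class = "atraflux_domain_error")
  expect_error(capillary_density(2 * pm$L_C, pm), class = "atraflux_domain_error")
})

test_that("tidy() exposes every parameter with unit and category", {
  td <- tidy(atra_params("mouse"))
  expect_setequal(td$symbol, parameter_units()$symbol)
  expect_true(all(c("value", "unit", "category") %in% names(td)))
  expect_equal(td$value[td$symbol == "Ind_max"], 33)
})

test_that("shipped parameter files match the in-code presets", {
  for (cs in c("mouse-control", "mouse-feeding", "human-control")) {
    f <- system.file("extdata", paste0(cs, ".yaml"), package = "atraflux")
    expect_true(nzchar(f))
    p <- read_params(f)
    expect_identical(unclass(p), unclass(load_parameters(cs)))
  }
  m <- system.file("extdata", "parameter-units.csv", package = "atraflux")
  expect_equal(
    as.data.frame(readr::read_csv(m, show_col_types = FALSE)),
    as.data.frame(parameter_units())
  )
})
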