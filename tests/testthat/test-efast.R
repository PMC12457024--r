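ishigami <- function(x) {
  c(y = sin(x[[1]]) + 7 * sin(x[[2]])^2 + 0.1 * x[[3]]^4 * sin(x[[1]]))
}
ishigami_factors <- tibble::tibble(
  name = c("x1", "x2", "x3"), min = -pi, max = pi
)

test_that("search curves are deterministic and space-filling", {
  d <- efast_design(ishigami_factors, n = 65, M = 4, n_resample = 2, seed = 9)
  s1 <- efast_sample(d)
  s2 <- efast_sample(d)
  expect_identical(s1, s2)
  for (nm in c("x1", "x2", "x3")) {
    expect_lt(min(s1[[nm]]), -pi + 0.01 * 2 * pi)
    expect_gt(max(s1[[nm]]), pi - 0.01 * 2 * pi)
  }
  expect_equal(nrow(s1), 3 * 2 * 65)
})

test_that("frequency assignment respects the interference condition", {
  d <- efast_design(ishigami_factors, n = 65, M = 4)
  expect_equal(d$omega1, 8) # floor((65-1)/(2*4))
  om <- efast_frequencies(k = 3, omega1 = 8, M = 4)
  expect_length(om, 2)
  expect_true(all(om <= max(1, 8 / (2 * 4))))
  # with a generous budget the complementary frequencies spread out
  om2 <- efast_frequencies(k = 4, omega1 = 64, M = 4)
  expect_true(all(diff(om2) > 0))
  expect_true(all(om2 <= 8))
  expect_error(efast_design(ishigami_factors, n = 10, M = 4),
    class = "atraflux_design_error"
  )
  expect_error(
    efast_design(tibble::tibble(name = "x", min = 1, max = 0)),
    class = "atraflux_design_error"
  )
})

test_that("total indices reproduce the Ishigami benchmark", {
  d <- efast_design(ishigami_factors, n = 257, M = 4, n_resample = 2, seed = 4)
  res <- efast_total_index(ishigami, d)
  st <- res$S_T[match(c("x1", "x2", "x3"), res$parameter)]
  # analytic total-order indices for a = 7, b = 0.1
  expect_lt(abs(st[1] - 0.5574), 0.05)
  expect_lt(abs(st[2] - 0.4424), 0.05)
  expect_lt(abs(st[3] - 0.2436), 0.05)
})

test_that("an ignored parameter scores at the dummy noise floor", {
  f <- function(x) c(y = sin(x[[1]]))
  fac <- tibble::tibble(name = c("x1", "inert", "dummy"), min = c(-pi, 0, 0), max = c(pi, 1, 1))
  d <- efast_design(fac, n = 129, M = 4, n_resample = 2, seed = 2)
  res <- efast_total_index(f, d)
  st <- setNames(res$S_T, res$parameter)
  expect_gt(st["x1"], 0.9)
  expect_lt(st["inert"], 2 * max(st["dummy"], 0.05))
  # directions: monotone dependence detected, inert indeterminate
  dir <- setNames(res$direction, res$parameter)
  g <- function(x) c(y = x[[1]]^3)
  resg <- efast_total_index(g, d)
  expect_equal(resg$direction[resg$parameter == "x1"], "+")
  expect_equal(dir[["inert"]], "indeterminate")
})

test_that("resampling spread of the indices is small for the default design", {
  d <- efast_design(ishigami_factors, n = 65, M = 4, n_resample = 5, seed = 3)
  res <- efast_total_index(ishigami, d)
  expect_true(all(res$S_T_se < 0.05))
})

test_that("failed evaluations are imputed up to the failure budget", {
  flaky <- local({
    k <- 0
    function(x) {
      k <<- k + 1
      if (k %% 40 == 0) stop("solver hiccup")
      c(y = sin(x[[1]]))
    }
  })
  fac <- tibble::tibble(name = c("x1", "x2"), min = c(-pi, 0), max = c(pi, 1))
  d <- efast_design(fac, n = 65, M = 4, n_resample = 1, seed = 8)
  res <- efast_total_index(flaky, d)
  expect_gt(attr(res, "n_failed"), 0)
  always_fail <- function(x) stop("no")
  expect_error(efast_total_index(always_fail, d), class = "atraflux_solver_error")
})

test_that("transport-model factor tables carry the study ranges", {
  p <- atra_params("mouse")
  ff <- efast_factors(p, "fluid")
  expect_setequal(ff$name, c("K_S", "Lp_star", "beta", "u_RPE", "dP_blood", "dP_SCS", "dummy"))
  expect_equal(ff$min[ff$name == "K_S"], 0.5 * p$K_S)
  expect_equal(ff$max[ff$name == "Lp_star"], 3 * p$Lp_star)
  expect_equal(ff$min[ff$name == "dP_blood"], 3 * 133.322)
  fa <- efast_factors(p, "atra")
  expect_true(all(c("k_prod", "k_CYP_deg", "Ind_C50", "c3_B") %in% fa$name))
})
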