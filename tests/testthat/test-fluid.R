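test_that("Goldmann balance partitions aqueous production linearly in IOP", {
  p <- atra_params("human")
  expect_equal(goldmann_outflow(p$EVP, p), p$Q_prod)
  # at the reference human IOP the unconventional share is just under 20%
  q <- goldmann_outflow(14.9 * 133.322, p)
  expect_rel(q / p$Q_prod, 0.1984, 0.005)
  expect_rel(q, 0.502e-9 / 60, 0.005) # ~0.502 ul/min
})

test_that("Starling source vanishes at equilibrium and where capillaries are absent", {
  p <- atra_params("human")
  iop <- 15 * 133.322
  p_B <- iop + p$dP_blood
  expect_equal(
    starling_source(0, p_B, p$c_SA_blood_total, iop, p), 0
  )
  plateau <- starling_source(0, iop, p$c_SA_blood_total, iop, p)
  expect_lt(abs(starling_source(p$L_C, iop, p$c_SA_blood_total, iop, p)),
    1e-10 * abs(plateau)
  )
})

test_that("hydrostatic-only filtration at the RPE matches the lumped estimate", {
  # with tissue concentration equal to blood and tissue pressure pinned at
  # the suprachoroidal value, q(0) ~ (1/alpha) Lp* (dPb + dPscs); exact up
  # to the residual logistic tail 1/(1 + exp(Gamma*alpha)) of the capillary
  # step at x = 0
  for (sp in c("mouse", "human")) {
    p <- atra_params(sp)
    iop <- 14.9 * 133.322
    q0 <- starling_source(0, iop - p$dP_SCS, p$c_SA_blood_total, iop, p)
    tol <- max(0.02, 2 / (1 + exp(p$Gamma * p$alpha)))
    expect_rel(q0, (1 / p$alpha) * p$Lp_star * (p$dP_blood + p$dP_SCS), tol)
  }
})

test_that("solver reproduces the closed-form IOP in the no-filtration limit", {
  for (sp in c("mouse", "human")) {
    p <- atra_params(sp, Lp_star = 0, u_RPE = 0)
    g <- make_grid(p, 120, 120)
    sol <- solve_fluid(p, g)
    expect_rel(sol$iop, closed_form_iop(p), 1e-8)
    # no filtration: superficial velocity uniform per layer
    expect_lt(diff(range(sol$u_sclera)) / abs(mean(sol$u_sclera)), 1e-8)
  }
})

test_that("pressure field satisfies its boundary and interface conditions", {
  for (case in c("human-control", "mouse-control")) {
    fit <- ref_fit(case)
    p <- fit$params
    fl <- fit$fluid
    N <- length(fl$x)
    i_if <- fl$i_if
    # SCS offset and orbital pressure
    expect_rel(fl$p[i_if], fl$iop - p$dP_SCS, 1e-9)
    expect_rel(fl$p[N], p$p_orbit, 1e-9)
    # scleral pressure is affine: second differences vanish
    ps <- fl$p[i_if:N]
    xs <- fl$x[i_if:N]
    slope <- diff(ps) / diff(xs)
    expect_lt(diff(range(slope)) / abs(mean(slope)), 1e-6)
    # velocity jump at the interface equals Qu/A_S
    expect_rel(fl$u_sclera[1] - fl$u_choroid[i_if], fl$Q_u / p$A_S, 1e-6)
    # global mass balance to 0.1%:
    # A_S u(out) - A_S int(q) = A_S u_RPE + Qu
    lhs <- p$A_S * fl$u_sclera[length(fl$u_sclera)] -
      p$A_S * atraflux:::trapz(fl$x[1:i_if], fl$q[1:i_if])
    rhs <- p$A_S * p$u_RPE + fl$Q_u
    expect_rel(lhs, rhs, 1e-3)
  }
})

test_that("velocity signs match the species-specific flow patterns", {
  # mouse: outward flow everywhere; human: slight reversal in outer choroid
  m <- ref_fit("mouse-control")$fluid
  expect_true(all(m$u_choroid > 0) && all(m$u_sclera > 0))
  h <- ref_fit("human-control")$fluid
  expect_lt(min(h$u_choroid), 0)
  expect_gt(h$u_sclera[length(h$u_sclera)], 0)
})

test_that("raising capillary conductivity lowers IOP and scleral outflow", {
  p0 <- atra_params("human")
  g <- make_grid(p0, 150, 150)
  res <- lapply(c(0.5, 1, 2), function(f) {
    fit <- solve_steady_state(atra_params("human", Lp_star = f * p0$Lp_star), g)
    fit$summary
  })
  iops <- vapply(res, function(s) s$iop_mmHg, numeric(1))
  us <- vapply(res, function(s) s$u_S, numeric(1))
  expect_true(all(diff(iops) < 0))
  expect_true(all(diff(us) < 0))
})

test_that("IOP is insensitive to doubling the default grid resolution", {
  p <- atra_params("human")
  i1 <- solve_steady_state(p, make_grid(p, 400, 400))$summary$iop_mmHg
  i2 <- solve_steady_state(p, make_grid(p, 800, 800))$summary$iop_mmHg
  expect_lt(abs(i1 - i2), 0.01)
})

test_that("numerical solution converges to the sharp-step analytic oracle", {
  # large Gamma with uniform blood-level concentrations: the smoothed step
  # approaches an indicator profile with a piecewise-analytic solution
  base <- atra_params("human")
  oracle <- step_fluid_oracle(base)
  errs <- vapply(c(200, 800, 3200), function(gam) {
    p <- atra_params("human", Gamma = gam)
    g <- make_grid(p, 600, 150, refine = 8)
    sol <- solve_fluid(p, g) # c_total = blood level
    abs(sol$iop - oracle$iop) / oracle$iop
  }, numeric(1))
  expect_lt(errs[3], 5e-4)
  expect_true(all(diff(errs) < 0)) # error shrinks as Gamma grows
})

test_that("uveovortex/uveoscleral partition matches species physiology", {
  part_h <- partition_outflow(ref_fit("human-control")$fluid, ref_params("human-control"))
  part_m <- partition_outflow(ref_fit("mouse-control")$fluid, ref_params("mouse-control"))
  expect_gt(part_h$drainage_ratio, 1)
  expect_lt(part_m$drainage_ratio, 1)
  expect_rel(part_h$uveovortex_fraction + part_h$uveoscleral_fraction, 1, 1e-3)
  # no transmural conductivity, no uveovortex drainage
  p0 <- atra_params("human", Lp_star = 0)
  g <- make_grid(p0, 120, 120)
  part0 <- partition_outflow(solve_fluid(p0, g), p0)
  expect_equal(part0$uveovortex_fraction, 0, tolerance = 1e-10)
})
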