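test_that("CYP26 degradation rate has the induced Michaelis-Menten form", {
  p <- atra_params("mouse")
  expect_equal(degradation_rate(0, p), 0)
  # half saturation by construction at c3 = f_u_inc * Ind_C50
  c_half <- p$f_u_inc * p$Ind_C50
  expect_equal(
    degradation_rate(c_half, p),
    p$k_CYP_deg * (p$Ind_max / 2) * c_half
  )
  # strictly increasing, superlinear below saturation, asymptotically linear
  c3 <- 10^seq(-9, 1, length.out = 60)
  r <- degradation_rate(c3, p)
  expect_true(all(diff(r) > 0))
  expect_rel(r[60] / c3[60], p$k_CYP_deg * p$Ind_max, 1e-3)
  low <- c3 < 1e-6
  expect_true(all(diff((r / c3)[low]) > 0)) # effective rate grows with c3
  expect_error(degradation_rate(-1e-9, p), class = "atraflux_domain_error")
})

test_that("unbound fraction spans the reported 0.2-1.5% range at tissue albumin levels", {
  expect_equal(unbound_fraction(0, 2e-4), 1)
  expect_equal(round(100 * unbound_fraction(2.3e6, 2e-4), 1), 0.2)
  expect_equal(round(100 * unbound_fraction(3.3e5, 2e-4), 1), 1.5)
})

test_that("transmural exchange is linear and vanishes at blood equilibrium", {
  p <- atra_params("mouse")
  x <- p$alpha * p$L_C / 2
  expect_equal(transmural_exchange(x, 0.2, 0.2, p), 0)
  b1 <- transmural_exchange(x, 0.1, 0.4, p)
  p2 <- p
  p2$beta <- 2 * p$beta
  expect_equal(transmural_exchange(x, 0.1, 0.4, p2), 2 * b1)
  # back-leakage when tissue exceeds blood
  expect_lt(transmural_exchange(x, 0.5, 0.4, p), 0)
})

test_that("without sources the concentrations are identically zero", {
  p <- atra_params("mouse", beta = 0, k_prod = 0)
  g <- make_grid(p, 100, 100)
  fl <- solve_fluid(p, g)
  so <- solve_solute(p, g, fl)
  expect_equal(max(abs(so$c2)), 0)
  expect_equal(max(abs(so$c3)), 0)
})

test_that("scleral profile matches the constant-coefficient analytic solution", {
  # with Ind_C50 pushed to zero the induction bracket saturates at Ind_max,
  # making the scleral sink linear: u c' - D c'' = -g c with constant g.
  # Matching the numeric interface concentration, the analytic solution
  # with a zero-gradient outer boundary is a sum of two exponentials.
  p <- atra_params("mouse", Ind_C50 = 1e-30)
  g <- make_grid(p, 300, 300)
  fit <- solve_steady_state(p, g)
  so <- fit$solute
  fl <- fit$fluid
  u <- fl$u_sclera[length(fl$u_sclera)]
  D <- p$D3_S
  gam <- p$k_CYP_deg * p$Ind_max
  disc <- sqrt(u^2 + 4 * D * gam)
  r1 <- (u + disc) / (2 * D)
  r2 <- (u - disc) / (2 * D)
  xs <- so$x[so$i_if:length(so$x)] - p$L_C
  c_if <- so$c3[so$i_if]
  L <- p$L_S
  # solve for the two amplitudes from c(0) = c_if and c'(L) = 0
  Amat <- rbind(c(1, 1), c(r1 * exp(r1 * L), r2 * exp(r2 * L)))
  ab <- solve(Amat, c(c_if, 0))
  c_exact <- ab[1] * exp(r1 * xs) + ab[2] * exp(r2 * xs)
  expect_lt(max(abs(so$c3[so$i_if:length(so$x)] - c_exact)) / c_if, 5e-3)
})

test_that("converged profiles satisfy boundary, interface and balance conditions", {
  for (case in c("mouse-control", "mouse-feeding", "human-control")) {
    fit <- ref_fit(case)
    p <- fit$params
    so <- fit$solute
    fl <- fit$fluid
    N <- length(so$x)
    i_if <- so$i_if
    sc <- i_if:N
    ch <- 1:i_if
    a <- capillary_density(so$x[ch], p)

    expect_true(all(so$c2 >= 0) && all(so$c3 >= 0))

    for (species in list(
      list(c = so$c2, D_C = p$D2_C, D_S = p$D2_S),
      list(c = so$c3, D_C = p$D3_C, D_S = p$D3_S)
    )) {
      c_ <- species$c
      scale <- max(abs(c_)) * max(abs(fl$u_choroid))
      # no-flux at the RPE
      grad0 <- sum(atraflux:::fd_weights(so$x[1:3], so$x[1], 1) * c_[1:3])
      expect_lt(abs(fl$u_choroid[1] * c_[1] - species$D_C * grad0), 1e-6 * scale)
      # zero gradient at the orbit
      gradN <- sum(atraflux:::fd_weights(so$x[N - (0:2)], so$x[N], 1) * c_[N - (0:2)])
      expect_lt(abs(species$D_S * gradN), 1e-6 * scale)
      # total-flux continuity across the interface (advective jump included)
      gm <- sum(atraflux:::fd_weights(so$x[i_if - (0:2)], so$x[i_if], 1) * c_[i_if - (0:2)])
      gp <- sum(atraflux:::fd_weights(so$x[i_if + (0:2)], so$x[i_if], 1) * c_[i_if + (0:2)])
      Jm <- fl$u_choroid[i_if] * c_[i_if] - species$D_C * gm
      Jp <- fl$u_sclera[1] * c_[i_if] - species$D_S * gp
      expect_lt(abs(Jm - Jp), 1e-4 * scale)
    }

    # species-wise global balance to 0.5%:
    # atRA:SA: synthesis + transmural influx = scleral sink + orbit efflux
    tz <- atraflux:::trapz
    synth <- tz(so$x[ch], p$k_prod * a)
    leak3 <- tz(so$x[ch], p$beta * a * (p$c3_B - so$c3[ch]))
    cons <- tz(so$x[sc], so$r3[sc])
    out3 <- fl$u_sclera[length(fl$u_sclera)] * so$c3[N]
    expect_rel(synth + leak3, cons + out3, 5e-3)
    # SA: transmural influx + scleral release = binding sink + orbit efflux
    c2_B <- p$c_SA_blood_total - p$c3_B
    leak2 <- tz(so$x[ch], p$beta * a * (c2_B - so$c2[ch]))
    out2 <- fl$u_sclera[length(fl$u_sclera)] * so$c2[N]
    expect_rel(leak2 + cons, synth + out2, 5e-3)
  }
})

test_that("albumin is nearly conserved and scleral transport is advective", {
  fit <- ref_fit("human-control")
  p <- fit$params
  so <- fit$solute
  # reactions perturb SA by <1% in non-feeding conditions (small Damkohler)
  p_norx <- p
  p_norx$k_prod <- 0
  p_norx$k_CYP_deg <- 0
  so2 <- solve_solute(p_norx, fit$grid, fit$fluid)
  expect_lt(max(abs(so2$c2 - so$c2)) / max(so$c2), 0.01)

  # in the sclera the combined SA + atRA:SA flux is constant and advective
  N <- length(so$x)
  sc <- (so$i_if + 1):N
  J_tot <- so$J_adv_2[sc] + so$J_adv_3[sc] + so$J_diff_2[sc] + so$J_diff_3[sc]
  expect_lt(diff(range(J_tot)) / abs(mean(J_tot)), 5e-3)
  expect_lt(max(abs(so$J_diff_2[sc])) / max(abs(so$J_adv_2[sc])), 5e-3)
})

test_that("feeding swaps trace atRA for a visible SA exchange across the sclera", {
  ctl <- ref_fit("mouse-control")$solute
  fed <- ref_fit("mouse-feeding")$solute
  N <- length(ctl$x)
  sc <- (ctl$i_if + 1):N
  # trace regime: atRA:SA orders of magnitude below SA
  expect_lt(max(ctl$c3 / ctl$c2), 1e-3)
  # under feeding, SA release mirrors atRA:SA degradation: their sum is
  # conserved across the sclera
  tot <- fed$c2[sc] + fed$c3[sc]
  expect_lt(diff(range(tot)) / mean(tot), 1e-3)
  expect_gt(fed$c2[N] - fed$c2[sc[1]], 0) # SA rises as atRA:SA falls
  expect_lt(fed$c3[N] - fed$c3[sc[1]], 0)
})

test_that("scleral consumption-rate profile decreases outward in all cases", {
  for (case in c("mouse-control", "mouse-feeding", "human-control")) {
    so <- ref_fit(case)$solute
    r <- so$r3[(so$i_if + 1):length(so$x)]
    # nonincreasing outward (the outer zero-gradient node is flat)
    expect_true(all(diff(r) < 1e-10 * max(r)))
  }
})
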