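# Shared fixtures: reference coupled solves are memoised so the three
# standard cases are computed once per test run.

.case_cache <- new.env(parent = emptyenv())

ref_params <- function(case) {
  parts <- strsplit(case, "-", fixed = TRUE)[[1]]
  atra_params(parts[1], parts[2])
}

# production-resolution coupled solve, cached
ref_fit <- function(case, n = 400) {
  key <- paste(case, n, sep = "@")
  if (is.null(.case_cache[[key]])) {
    p <- ref_params(case)
    .case_cache[[key]] <- solve_steady_state(p, make_grid(p, n, n))
  }
  .case_cache[[key]]
}

ref_summary <- function(case, n = 400) ref_fit(case, n)$summary

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# Piecewise-analytic fluid oracle for an exact indicator capillary profile
# (height 1/alpha on [0, alpha*L_C]): cosh/sinh pressure in the capillary
# region, affine outside, affine in the sclera, IOP from the Goldmann
# closure. Assembled as an independent 6x6 linear system in the unknowns
# (A, B, c2, m2, m3, IOP); valid for a uniform tissue albumin concentration
# equal to blood (zero osmotic difference).
step_fluid_oracle <- function(params) {
  mu <- params$mu
  K_C <- params$K_C
  K_S <- params$K_S
  L_C <- params$L_C
  L_S <- params$L_S
  x1 <- params$alpha * L_C
  lam <- sqrt(mu * params$Lp_star / (params$alpha * K_C))
  M <- matrix(0, 6, 6)
  rhs <- numeric(6)
  # unknowns: A, B, c2, m2, m3, IOP;  region 1: p = IOP + dP_blood + A ch + B sh
  # region 2: p = c2 + m2 x;  sclera: p = (IOP - dP_SCS) + m3 (x - L_C)
  M[1, 2] <- lam # p'(0) = -mu u_RPE / K_C
  rhs[1] <- -mu * params$u_RPE / K_C
  M[2, ] <- c(cosh(lam * x1), sinh(lam * x1), -1, -x1, 0, 1) # continuity at x1
  rhs[2] <- -params$dP_blood
  M[3, ] <- c(lam * sinh(lam * x1), lam * cosh(lam * x1), 0, -1, 0, 0)
  M[4, ] <- c(0, 0, 1, L_C, 0, -1) # p(L_C) = IOP - dP_SCS
  rhs[4] <- -params$dP_SCS
  # flux jump: -K_C/mu m2 + (Q_prod - C (IOP - EVP))/A_S = -K_S/mu m3
  M[5, ] <- c(0, 0, 0, -K_C / mu, K_S / mu, -params$C_fac / params$A_S)
  rhs[5] <- -(params$Q_prod + params$C_fac * params$EVP) / params$A_S
  M[6, ] <- c(0, 0, 0, 0, L_S, 1) # outer: IOP - dP_SCS + m3 L_S = p_orbit
  rhs[6] <- params$p_orbit + params$dP_SCS
  sc <- apply(abs(M), 1, max)
  sol <- solve(M / sc, rhs / sc)
  names(sol) <- c("A", "B", "c2", "m2", "m3", "iop")
  as.list(sol)
}

# closed-form IOP for the no-filtration, no-pumping limit (Lp* = u_RPE = 0):
# the scleral pressure drop carries the whole unconventional outflow
closed_form_iop <- function(params) {
  kappa <- params$K_S * params$A_S / (params$mu * params$L_S)
  (params$Q_prod + params$C_fac * params$EVP +
    kappa * (params$p_orbit + params$dP_SCS)) / (params$C_fac + kappa)
}
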