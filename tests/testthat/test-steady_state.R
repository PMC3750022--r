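test_that("the phosphatase-dead mutant is bistable at defaults, the wild type graded", {
  t281r <- default_params("T281R")
  ss <- find_steady_states(t281r)
  expect_length(ss$Pstar, 3)
  expect_equal(ss$stability, c("stable", "unstable", "stable"))
  expect_equal(ss$regime, "bistable")
  # every state annihilates the right-hand side
  for (k in 1:3) {
    r <- reduced_rhs(ss$states[k, ], t281r)
    expect_lt(max(abs(r)) / (t281r$lam * (1 + sum(ss$states[k, ]))), 1e-9)
  }
  # wild type: exactly one stable state for every kinase rate
  wt <- default_params("wild_type")
  for (kk in 10^seq(-4, 0, length.out = 9)) {
    p <- reduced_params(k_k = kk, k_p = wt$k_p, V_0 = wt$V_0,
                        V_f = wt$V_f, K_f = wt$K_f, h = wt$h,
                        lam = wt$lam)
    s <- find_steady_states(p, classify = FALSE)
    expect_length(s$Pstar, 1)
    expect_equal(s$stability, "stable")
  }
})

test_that("without production the origin is the unique stable state", {
  p <- reduced_params(k_k = 0, k_p = 0, V_0 = 0, V_f = 0, K_f = 1,
                      lam = 0.1)
  ss <- find_steady_states(p, classify = FALSE)
  expect_equal(ss$Pstar, 0)
  expect_equal(ss$stability, "stable")
  expect_equal(jacobian_stability(p, c(P = 0, Q = 0, Pstar = 0)),
               "stable")
})

test_that("solver agrees with the dense-grid oracle on random circuits", {
  expect_equal(oracle_disagreements(60, seed = 91), 0L)
})

test_that("stability labels match the forward-integration fate of perturbations", {
  p <- default_params("T281R")
  ss <- find_steady_states(p)
  mid <- ss$states[2, ]
  integrate_from <- function(y0, t_end = 4000) {
    sol <- deSolve::ode(y = y0, times = c(0, t_end), func = rhs_fun(p),
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
    unname(sol[nrow(sol), "Pstar"])
  }
  # middle state: perturbations diverge to the outer branches
  eps <- 1e-3
  lowered <- pmax(mid * (1 - eps), 0)
  raised <- mid * (1 + eps)
  expect_equal(integrate_from(lowered), ss$Pstar[1], tolerance = 1e-3)
  expect_equal(integrate_from(raised), ss$Pstar[3], tolerance = 1e-3)
  expect_equal(jacobian_stability(p, mid), "unstable")
  # outer states: perturbations return
  for (k in c(1, 3)) {
    st <- ss$states[k, ]
    expect_equal(integrate_from(st * 1.05), ss$Pstar[k],
                 tolerance = 1e-3)
    expect_equal(jacobian_stability(p, st), "stable")
  }
  expect_error(jacobian_stability(p, mid * 3), "not a steady state")
})

test_that("hysteresis: integration selects the branch matching its history", {
  p <- default_params("T281R")
  ss <- find_steady_states(p)
  run_to_ss <- function(y0) {
    sol <- deSolve::ode(y = y0, times = c(0, 6000), func = rhs_fun(p),
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
    unname(sol[nrow(sol), "Pstar"])
  }
  expect_equal(run_to_ss(c(P = 1e-4, Q = 1e-4, Pstar = 1e-4)),
               ss$Pstar[1], tolerance = 1e-4)
  hi <- pstar_upper <- (p$V_0 + p$V_f) / p$lam
  expect_equal(run_to_ss(c(P = hi / 2, Q = hi, Pstar = hi / 2)),
               ss$Pstar[3], tolerance = 1e-4)
})

test_that("regime classification follows the stable-state count and reference scale", {
  p <- default_params("T281R")
  ss <- find_steady_states(p, classify = FALSE)
  expect_equal(classify_regime(ss), "bistable")
  fake <- function(Pstar, stability) {
    s <- ss
    s$Pstar <- Pstar
    s$stability <- stability
    s$states <- matrix(Pstar, ncol = 1)
    s
  }
  expect_equal(classify_regime(fake(1e-3, "stable")), "monostable_off")
  expect_equal(classify_regime(fake(50, "stable")), "monostable_on")
  expect_equal(classify_regime(fake(1, "stable"), ref_scale = 0.1),
               "monostable_on")
  expect_error(classify_regime(fake(c(1, 2, 3), rep("stable", 3))),
               "more than two stable")
  expect_error(classify_regime(fake(numeric(0), character(0))), "empty")
})

test_that("display clamping floors values at 1e-4", {
  expect_equal(clamp_for_display(1e-6), 1e-4)
  expect_equal(clamp_for_display(0.5), 0.5)
  expect_equal(clamp_for_display(1e-4), 1e-4)
  expect_equal(clamp_for_display(c(0, 1)), c(1e-4, 1))
  expect_error(clamp_for_display(-1), "nonnegative")
})

test_that("phosphatase sweep at low kinase rate shows the fold of the mutant branch", {
  t281r <- default_params("T281R")
  bt <- bifurcation_sweep(t281r, "k_p", 10^seq(-4, 0, length.out = 17))
  reg <- bt$table$regime
  expect_equal(reg[1], "bistable")
  expect_true(all(reg[reg != "bistable"] == "monostable_off"))
  expect_true(length(bt$folds) >= 1)
  # bistable cells all precede the monostable ones along increasing k_p
  expect_true(max(which(reg == "bistable")) < min(which(reg != "bistable")))
})

test_that("branch tables are continuous within branches and reproducible", {
  p <- default_params("T281R")
  grid <- 10^seq(-4, -2, length.out = 15)
  b1 <- bifurcation_sweep(p, "k_k", grid)
  b2 <- bifurcation_sweep(p, "k_k", grid)
  expect_identical(b1$table, b2$table)   # no randomness in this module
  # low branch continuity between adjacent grid points within a regime
  low <- b1$table$Pstar_low
  same <- b1$table$regime[-1] == b1$table$regime[-nrow(b1$table)]
  jumps <- abs(diff(low)) / pmax(low[-1], 1e-12)
  expect_true(all(jumps[same] < 1.5))
  expect_error(bifurcation_sweep(p, "k_k", c(1, 1, 2)), "monotone")
})

test_that("feedback-free circuits are never bistable in the scan", {
  p <- default_params("T281R")
  rmap <- bistability_scan(p, "k_p", 10^seq(-4, 0, length.out = 6),
                           "V_f", c(1e-12, 0.5, 1, 2), n_grid = 1500)
  tab <- rmap$table
  expect_true(all(tab$n_stable[tab$V_f == 1e-12] == 1))
  expect_true(all(tab$regime != "bistable" | tab$k_p < 0.1))
  expect_true(all(is.na(tab$display[tab$regime == "bistable"])))
  expect_true(all(tab$display[tab$regime != "bistable"] >= 1e-4))
  rmap2 <- bistability_scan(p, "k_p", 10^seq(-4, 0, length.out = 6),
                            "V_f", c(1e-12, 0.5, 1, 2), n_grid = 1500)
  expect_identical(rmap$table, rmap2$table)
})
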