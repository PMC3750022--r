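test_that("network construction mirrors the variant structure", {
  t281r <- default_params("T281R")
  net <- build_network(t281r, Omega = 100)
  expect_false("phosphatase" %in% names(net$reactions))
  wt <- build_network(default_params("wild_type"), Omega = 100)
  expect_true("phosphatase" %in% names(wt$reactions))
  dec <- build_network(default_params("decoupled"), Omega = 100)
  expect_equal(dec$reactions$prod_Q$type, 0)    # PhoP-P independent
  expect_error(build_network(t281r, Omega = 0.5), "Omega")
  # every reaction except production conserves the PhoP family
  for (nm in setdiff(names(net$reactions), c("prod", "prod_Q"))) {
    d <- net$reactions[[nm]]$delta
    pfam <- sum(d[intersect(names(d), c("P", "Pstar", "C_t", "C_p"))])
    expect_equal(pfam, 0)
  }
  detn <- build_network(default_params("T281R", model = "detailed"),
                        Omega = 100, scheme = "detailed")
  expect_false("cat_p" %in% names(detn$reactions))
  for (nm in setdiff(names(detn$reactions), "prod")) {
    d <- detn$reactions[[nm]]$delta
    pfam <- sum(d[intersect(names(d), c("P", "Pstar", "C_t", "C_p"))])
    qfam <- sum(d[intersect(names(d), c("Q", "Qstar", "C_t", "C_p"))])
    expect_equal(pfam, 0)
    expect_equal(qfam, 0)
  }
})

test_that("a silent network fires no reactions and divisions partition counts", {
  silent <- reduced_params(k_k = 0, k_p = 0, V_0 = 0, V_f = 0, K_f = 1,
                           lam = 0.1)
  net <- build_network(silent, Omega = 100)
  r0 <- gillespie_run(net, init = c(P = 0, Q = 0, Pstar = 0),
                      n_generations = 5, seed = 1)
  expect_equal(r0$steps, 0)
  expect_equal(unname(r0$final), c(0, 0, 0))
  # with counts present, binomial halving is the only dynamics
  r1 <- gillespie_run(net, init = c(P = 1000, Q = 0, Pstar = 0),
                      n_generations = 1, seed = 2)
  expect_equal(r1$steps, 0)
  expect_true(r1$final[["P"]] < 1000 && r1$final[["P"]] > 0)
  # zero generations returns the initial condition untouched
  r2 <- gillespie_run(net, init = c(P = 7, Q = 3, Pstar = 1),
                      n_generations = 0, seed = 3)
  expect_equal(unname(r2$final), c(7, 3, 1))
})

test_that("birth-death statistics match the analytic stationary law", {
  # production beta = V_0 * Omega, first-order dilution lam: stationary
  # distribution is Poisson(beta/lam)
  p <- reduced_params(k_k = 0, k_p = 0, V_0 = 0.01, V_f = 0, K_f = 1,
                      lam = 0.02)
  net <- build_network(p, Omega = 100)
  target <- 0.01 * 100 / 0.02   # 50
  ends <- run_ensemble(net, init = c(P = 50, Q = 50, Pstar = 0),
                       n_runs = 300, base_seed = 5, n_generations = 12,
                       policy = "dilution")
  m <- mean(ends$final_P)
  se <- sd(ends$final_P) / sqrt(nrow(ends))
  expect_lt(abs(m - target), 3 * se)
  disp <- var(ends$final_P) / m
  expect_lt(abs(disp - 1), 3 * sqrt(2 / nrow(ends)) + 0.1)
})

test_that("ensembles are deterministic given the base seed", {
  net <- build_network(default_params("T281R"), Omega = 50)
  e1 <- run_ensemble(net, init = c(P = 20, Q = 20, Pstar = 0),
                     n_runs = 5, base_seed = 42, n_generations = 3)
  e2 <- run_ensemble(net, init = c(P = 20, Q = 20, Pstar = 0),
                     n_runs = 5, base_seed = 42, n_generations = 3)
  expect_identical(e1, e2)
  e0 <- run_ensemble(net, n_runs = 0, base_seed = 1)
  expect_equal(nrow(e0), 0)
  expect_true(all(c("run", "seed", "mean_Pstar") %in% names(e0)))
})

test_that("the deterministic limit reproduces the rate equations", {
  p <- default_params("T281R")
  net <- build_network(p, Omega = 100)
  dl <- deterministic_limit(net)
  withr::with_seed(3, {
    for (i in 1:20) {
      st <- setNames(runif(3, 0, 40), c("P", "Q", "Pstar"))
      expect_equal(dl$rhs(st),
                   reduced_rhs(st[c("P", "Q", "Pstar")], p)[c("P", "Q",
                                                              "Pstar")],
                   tolerance = 1e-12)
    }
  })
  # birth-death network: dn/dt = beta - lam * n
  bd <- build_network(reduced_params(k_k = 0, k_p = 0, V_0 = 0.01,
                                     V_f = 0, K_f = 1, lam = 0.02),
                      Omega = 100)
  d <- deterministic_limit(bd)$rhs(c(P = 2, Q = 1, Pstar = 0))
  expect_equal(d[["P"]], 0.01 - 0.02 * 2)
  # unregistered propensity type is rejected
  broken <- net
  broken$reactions$kinase$type <- 9
  expect_error(deterministic_limit(broken)$rhs(c(P = 1, Q = 1,
                                                 Pstar = 1)),
               "no deterministic limit")
})

test_that("ensemble means track the ODE solution generation by generation", {
  p <- default_params("T281R")
  net <- build_network(p, Omega = 1e4)
  n_gen <- 10
  init <- c(P = 0, Q = 0, Pstar = 0)
  ends <- lapply(1:25, function(k)
    gillespie_run(net, init = init, n_generations = n_gen,
                  seed = 100 + k, policy = "dilution")$gen_means)
  mean_traj <- Reduce(`+`, ends) / length(ends)
  se_traj <- sqrt(Reduce(`+`, lapply(ends, function(m)
    (m - mean_traj)^2)) / (length(ends) - 1) / length(ends))
  # per-generation time averages of the ODE solution
  t_gen <- log(2) / p$lam
  times <- seq(0, n_gen * t_gen, length.out = 40 * n_gen + 1)
  sol <- deSolve::ode(y = init, times = times, func = rhs_fun(p),
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  gen_of <- pmin(floor(times[-1] / t_gen), n_gen - 1) + 1
  for (sp in c("P", "Q", "Pstar")) {
    ode_avg <- tapply(sol[-1, sp], gen_of, mean) * 1e4
    dev <- abs(mean_traj[, sp] - ode_avg)
    expect_true(all(dev <= 3 * se_traj[, sp] + 0.02 * ode_avg + 1))
  }
})

test_that("switch detection respects the hysteresis band", {
  expect_error(detect_switch(1:5, 10, 5), "smaller")
  expect_equal(nrow(detect_switch(rep(1, 20), 5, 50)), 0)
  step <- c(rep(100, 5), rep(1, 5))
  ev <- detect_switch(step, 5, 50)
  expect_equal(ev$direction, "on_to_off")
  expect_equal(ev$generation, 6)
  # chatter within the band: no events
  band <- c(100, rep(c(20, 40), 8), 100)
  expect_equal(nrow(detect_switch(band, 5, 50)), 0)
  # full crossing both ways
  both <- c(rep(100, 3), rep(1, 3), rep(100, 3))
  expect_equal(detect_switch(both, 5, 50)$direction,
               c("on_to_off", "off_to_on"))
})

test_that("priming fraction counts threshold crossings of last-generation means", {
  ends <- data.frame(mean_Pstar = c(10, 2000, 15, 3000))
  expect_equal(priming_fraction(ends, 500), 50)
  expect_equal(priming_fraction(data.frame(mean_Pstar = c(1, 2)), 500), 0)
  expect_error(priming_fraction(ends[0, , drop = FALSE], 500), "empty")
  expect_error(priming_fraction(ends, -1), "threshold")
})

test_that("bimodality report separates mixtures from unimodal intermediates", {
  off_ref <- 1; on_ref <- 3000
  at_off <- data.frame(mean_Pstar = rep(off_ref, 50))
  expect_equal(unname(bimodality_report(at_off, off_ref, on_ref)),
               c(1, 0, 0))
  withr::with_seed(8, {
    mix <- data.frame(mean_Pstar = c(rpois(500, 2), rpois(500, 3000)))
    rep_mix <- bimodality_report(mix, off_ref, on_ref)
    expect_lt(rep_mix[["intermediate"]], 0.05)
    uni <- data.frame(mean_Pstar = rpois(1000, 55))  # geometric middle
    rep_uni <- bimodality_report(uni, off_ref, on_ref)
    expect_gt(rep_uni[["intermediate"]], 0.9)
  })
  expect_error(bimodality_report(at_off[0, , drop = FALSE], 1, 10),
               "empty")
})
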