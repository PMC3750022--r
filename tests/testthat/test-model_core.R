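test_that("promoter activity has the basal, half-saturation and plateau values", {
  expect_equal(promoter_activity(0, 0.1, 1, 0.5, 2), 0.1)
  for (h in c(1, 2, 4))
    expect_equal(promoter_activity(0.5, 0.1, 1, 0.5, h), 0.1 + 0.5)
  expect_equal(promoter_activity(1e6 * 0.5, 0.1, 1, 0.5, 1), 1.1,
               tolerance = 1e-6)
  expect_error(promoter_activity(-1, 0.1, 1, 0.5, 1), "nonnegative")
  expect_error(promoter_activity(1, 0.1, 1, 0, 1), "K_f")
})

test_that("promoter activity is bounded and monotone for random parameters", {
  withr::with_seed(11, {
    for (i in 1:50) {
      V_0 <- runif(1); V_f <- runif(1, 0, 5); K_f <- 10^runif(1, -2, 2)
      h <- runif(1, 1, 4)
      s <- sort(10^runif(100, -4, 4))
      v <- promoter_activity(s, V_0, V_f, K_f, h)
      expect_true(all(v >= V_0 - 1e-12 & v <= V_0 + V_f + 1e-12))
      expect_true(all(diff(v) >= -1e-12))
    }
  })
})

test_that("reduced model conserves protein-family fluxes", {
  p0 <- reduced_params(k_k = 0.5, k_p = 0.2, V_0 = 0, V_f = 1, K_f = 1,
                       lam = 0.1)
  expect_equal(reduced_rhs(c(P = 0, Q = 0, Pstar = 0), p0),
               c(P = 0, Q = 0, Pstar = 0))
  # flux bookkeeping at a reference state
  p <- reduced_params(k_k = 0.3, k_p = 0.1, V_0 = 0.05, V_f = 2,
                      K_f = 0.7, h = 2, lam = 0.04)
  d <- reduced_rhs(c(P = 1, Q = 1, Pstar = 1), p)
  f <- promoter_activity(1, p$V_0, p$V_f, p$K_f, p$h)
  expect_equal(d[["P"]] + d[["Pstar"]], f - 2 * p$lam)
  expect_equal(d[["Q"]], f - p$lam)
})

test_that("mass bookkeeping identities hold for random states and parameters", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      p <- reduced_params(k_k = runif(1), k_p = runif(1), V_0 = runif(1),
                          V_f = runif(1, 0, 3), K_f = runif(1, 0.1, 5),
                          h = runif(1, 1, 3), lam = runif(1, 0.01, 0.5))
      st <- runif(3, 0, 10)
      names(st) <- c("P", "Q", "Pstar")
      d <- reduced_rhs(st, p)
      f <- promoter_activity(st[["Pstar"]], p$V_0, p$V_f, p$K_f, p$h)
      expect_equal(d[["P"]] + d[["Pstar"]],
                   f - p$lam * (st[["P"]] + st[["Pstar"]]),
                   tolerance = 1e-10)
      expect_equal(d[["Q"]], f - p$lam * st[["Q"]], tolerance = 1e-10)
    }
  })
})

test_that("detailed model conserves PhoP and PhoQ family totals", {
  p <- default_params("wild_type", model = "detailed")
  zero <- setNames(rep(0, 6), c("P", "Pstar", "Q", "Qstar", "C_t", "C_p"))
  pz <- detailed_params(V_0 = 0, V_f = 1, K_f = 5, lam = 0.02, k_a = 1,
                        k_on_t = 0.1, k_off_t = 10, k_cat_t = 1,
                        k_on_p = 1, k_off_p = 10, k_cat_p = 5)
  expect_equal(unname(detailed_rhs(zero, pz)), rep(0, 6))
  ones <- setNames(rep(1, 6), names(zero))
  d <- detailed_rhs(ones, p)
  f <- promoter_activity(1, p$V_0, p$V_f, p$K_f, p$h)
  # PhoP family: P + Pstar + C_t + C_p
  expect_equal(d[["P"]] + d[["Pstar"]] + d[["C_t"]] + d[["C_p"]],
               f - p$lam * 4)
  # PhoQ family: Q + Qstar + C_t + C_p
  expect_equal(d[["Q"]] + d[["Qstar"]] + d[["C_t"]] + d[["C_p"]],
               f - p$lam * 4)
  withr::with_seed(13, {
    for (i in 1:1000) {
      st <- setNames(runif(6, 0, 5), names(zero))
      d <- detailed_rhs(st, p)
      f <- promoter_activity(st[["Pstar"]], p$V_0, p$V_f, p$K_f, p$h)
      sP <- st[["P"]] + st[["Pstar"]] + st[["C_t"]] + st[["C_p"]]
      sQ <- st[["Q"]] + st[["Qstar"]] + st[["C_t"]] + st[["C_p"]]
      expect_equal(d[["P"]] + d[["Pstar"]] + d[["C_t"]] + d[["C_p"]],
                   f - p$lam * sP, tolerance = 1e-9)
      expect_equal(d[["Q"]] + d[["Qstar"]] + d[["C_t"]] + d[["C_p"]],
                   f - p$lam * sQ, tolerance = 1e-9)
    }
  })
})

test_that("detailed steady states approach the reduced model in the fast-exchange limit", {
  red <- default_params("T281R")
  # binding equilibrates fast relative to catalysis; effective kinase
  # constant k_cat_t/K_t matches the reduced k_k; autophosphorylation
  # fast so the free kinase pool is phospho-PhoQ
  k_on_t <- 20; k_off_t <- 20000
  k_cat_t <- red$k_k * (k_off_t + red$lam) / k_on_t /
    (1 - red$k_k / k_on_t)
  det <- detailed_params(V_0 = red$V_0, V_f = red$V_f, K_f = red$K_f,
                         h = red$h, lam = red$lam, k_a = 100,
                         k_on_t = k_on_t, k_off_t = k_off_t,
                         k_cat_t = k_cat_t, k_on_p = 1, k_off_p = 1000,
                         k_cat_p = 0)
  ss_red <- find_steady_states(red)
  ss_det <- find_steady_states(det)
  expect_equal(length(ss_det$Pstar), length(ss_red$Pstar))
  expect_equal(ss_det$Pstar, ss_red$Pstar, tolerance = 0.05)
})

test_that("decoupled model clamps PhoQ and keeps PhoP-family bookkeeping", {
  p <- decoupled_params(k_k = 0.1, V_0 = 0.005, V_f = 1, K_f = 5,
                        lam = 0.02, Q_tot = 3)
  st <- c(P = 2, Pstar = 1, C_p = 0)
  d <- decoupled_rhs(st, p)
  f <- promoter_activity(1, p$V_0, p$V_f, p$K_f, p$h)
  expect_equal(d[["P"]] + d[["Pstar"]] + d[["C_p"]], f - p$lam * 3)
  # no PhoQ -> no kinase flux, Pstar decays from any start
  p0 <- decoupled_params(k_k = 0.1, V_0 = 0.005, V_f = 1, K_f = 5,
                         lam = 0.02, Q_tot = 0)
  d0 <- decoupled_rhs(c(P = 5, Pstar = 4, C_p = 0), p0)
  expect_equal(d0[["Pstar"]], -p0$lam * 4)
  expect_error(decoupled_params(k_k = 0.1, V_0 = 0.005, V_f = 1, K_f = 5,
                                lam = 0.02, Q_tot = -1), "negative")
  # sequestration: steady states match a dense scan of the balance
  psq <- decoupled_params(k_k = 0.1, V_0 = 0.005, V_f = 1, K_f = 5,
                          lam = 0.02, Q_tot = 3, K_d = 0.1)
  expect_equal(find_steady_states(psq, classify = FALSE)$Pstar,
               oracle_roots(psq), tolerance = 1e-6)
})

test_that("variant map reproduces the strain transformations", {
  base <- default_params("wild_type")
  expect_identical(make_variant(base, "wild_type"), base)
  t281r <- make_variant(base, "T281R")
  expect_equal(t281r$k_p, 0)
  expect_equal(t281r$k_k, 0.1 * base$k_k)
  dp2 <- make_variant(base, "T281R_dP2")
  expect_equal(dp2$k_p, 0)
  expect_equal(dp2$k_k, 0.1 * base$k_k)
  expect_equal(dp2$V_0, 0.1 * base$V_0)
  expect_gt(dp2$V_0, 0)   # residual basal transcription, not zero
  dec <- make_variant(base, "decoupled", Q_tot = 3)
  expect_s3_class(dec, "decoupled_params")
  expect_error(make_variant(base, "decoupled"), "Q_tot")
  expect_error(make_variant(base, "T281Q"), "arg")
  # detailed variant: phosphatase catalysis removed, kinase efficiency scaled
  detb <- default_params("wild_type", model = "detailed")
  dett <- make_variant(detb, "T281R")
  expect_equal(dett$k_cat_p, 0)
  expect_equal(dett$k_cat_t, 0.1 * detb$k_cat_t)
})

test_that("time rescaling leaves steady states invariant", {
  p <- default_params("T281R")
  expect_equal(rescale_time(p, 1), p)
  expect_error(rescale_time(p, 0), "positive")
  expect_error(rescale_time(p, -2), "positive")
  s1 <- find_steady_states(p, classify = FALSE)$Pstar
  s3 <- find_steady_states(rescale_time(p, 3), classify = FALSE)$Pstar
  expect_equal(s3, s1, tolerance = 1e-6)
  pd <- default_params("T281R", model = "detailed")
  expect_equal(find_steady_states(rescale_time(pd, 2.5),
                                  classify = FALSE)$Pstar,
               find_steady_states(pd, classify = FALSE)$Pstar,
               tolerance = 1e-6)
})

test_that("lowering growth rate is equivalent to upscaling all other rates", {
  p <- default_params("T281R")
  c_fac <- 2
  # lam / c with other rates fixed == all non-lam rates * c (up to the
  # overall time unit, which steady states ignore)
  p_slow <- unclass(p); p_slow$lam <- p$lam / c_fac
  p_slow <- do.call(reduced_params, p_slow[names(formals(reduced_params))])
  p_up <- rescale_time(p, c_fac)
  p_up <- unclass(p_up); p_up$lam <- p$lam
  p_up <- do.call(reduced_params, p_up[names(formals(reduced_params))])
  expect_equal(find_steady_states(p_up, classify = FALSE)$Pstar,
               find_steady_states(p_slow, classify = FALSE)$Pstar,
               tolerance = 1e-6)
})
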