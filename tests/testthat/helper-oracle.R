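# Independent brute-force oracle for the scalar steady-state balance of
# the reduced and decoupled models, written from first principles (its
# own Hill function, balance algebra, dense sign-change scan and plain
# bisection), so it shares no code path with find_steady_states().

oracle_hill <- function(s, p) {
  x <- (s / p$K_f)^p$h
  p$V_0 + p$V_f * x / (1 + x)
}

oracle_balance <- function(s, p) {
  if (inherits(p, "decoupled_params")) {
    if (is.finite(p$K_d)) {
      Kde <- p$K_d + p$lam / p$k_on_p
      Q <- p$Q_tot / (1 + s / Kde)
      Cp <- p$Q_tot * s / (Kde + s)
    } else {
      Q <- rep(p$Q_tot, length(s))
      Cp <- 0 * s
    }
    P <- oracle_hill(s, p) / p$lam - s - Cp
    ifelse(P < 0, -(1 + s),
           p$k_k * P * Q - p$k_p * s * Q - p$lam * (s + Cp))
  } else {
    Fv <- oracle_hill(s, p) / p$lam
    ifelse(Fv - s < 0, -(1 + s),
           p$k_k * (Fv - s) * Fv - p$k_p * s * Fv - p$lam * s)
  }
}

# Dense-grid sign-change scan (n >= 1e5 points) polished by bisection.
oracle_roots <- function(p, n = 2e5) {
  upper <- 1.05 * (p$V_0 + p$V_f) / p$lam
  s <- c(0, exp(seq(log(1e-10), log(max(upper, 1e-8)), length.out = n)))
  gv <- oracle_balance(s, p)
  idx <- which(diff(sign(gv)) != 0 & gv[-length(gv)] != 0)
  roots <- numeric(0)
  for (k in idx) {
    lo <- s[k]; hi <- s[k + 1]; flo <- gv[k]
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      fm <- oracle_balance(mid, p)
      if (fm == 0) { lo <- hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  if (any(gv == 0)) roots <- c(roots, s[gv == 0])
  sort(roots)
}

# Random parameter draws spanning phosphatase-dead, bifunctional and
# decoupled circuits.
draw_params <- function(kind = c("reduced", "reduced_nophos",
                                 "decoupled")) {
  kind <- match.arg(kind)
  lam <- 10^runif(1, -2, -1.3)
  V_0 <- 10^runif(1, -4, -1)
  V_f <- 10^runif(1, -0.7, 0.7)
  K_f <- 10^runif(1, -0.5, 1)
  h <- sample(1:2, 1)
  if (kind == "decoupled")
    decoupled_params(k_k = 10^runif(1, -3, 0), V_0 = V_0, V_f = V_f,
                     K_f = K_f, h = h, lam = lam,
                     Q_tot = 10^runif(1, -1, 2),
                     K_d = if (runif(1) < 0.5) Inf else 10^runif(1, -2, 1))
  else
    reduced_params(k_k = 10^runif(1, -5, -1),
                   k_p = if (kind == "reduced_nophos") 0
                         else 10^runif(1, -3, 0),
                   V_0 = V_0, V_f = V_f, K_f = K_f, h = h, lam = lam)
}

# Compare find_steady_states() against the oracle for n_draw random
# parameter sets; returns the number of disagreements.
oracle_disagreements <- function(n_draw, seed = 20240211) {
  withr::with_seed(seed, {
    bad <- 0L
    for (d in seq_len(n_draw)) {
      kind <- sample(c("reduced", "reduced_nophos", "decoupled"), 1)
      p <- draw_params(kind)
      orc <- oracle_roots(p)
      imp <- find_steady_states(p, classify = FALSE)$Pstar
      if (length(orc) != length(imp) ||
          max(abs(imp - orc) / pmax(orc, 1e-12)) > 1e-6)
        bad <- bad + 1L
    }
    bad
  })
}
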