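# Steady-state location by exact scalar reduction.
#
# For each model the steady-state conditions eliminate every species in
# favour of Pstar: production balances dilution of each conserved protein
# family, so total PhoP (and total PhoQ) equals f(Pstar)/lam, and the
# remaining phospho-flux balance is a single scalar equation g(Pstar) = 0.
# Roots of g are bracketed by sign changes on a log-spaced grid (plus 0)
# and polished by uniroot; this finds all roots in the window provided
# the grid resolves them, which the test suite verifies against a dense
# brute-force oracle.

# Scalar balance for the reduced model. Vectorized over s.
balance_reduced <- function(s, p) {
  Fv <- prod_rate(s, p) / p$lam           # total PhoP = total PhoQ
  g <- p$k_k * (Fv - s) * Fv - p$k_p * s * Fv - p$lam * s
  ifelse(Fv - s < 0, -(1 + s), g)         # P < 0: infeasible, negative sign
}

# Scalar balance for the decoupled model, with optional sequestration of
# PhoQ and PhoP-P into an inert complex (finite K_d). Uses the exact
# complex balance including dilution: C_p = s * Q / Kd_eff with
# Kd_eff = K_d + lam / k_on_p.
balance_decoupled <- function(s, p) {
  if (is.finite(p$K_d)) {
    Kde <- p$K_d + p$lam / p$k_on_p
    Q <- p$Q_tot / (1 + s / Kde)
    Cp <- p$Q_tot * s / (Kde + s)
  } else {
    Q <- rep(p$Q_tot, length(s))
    Cp <- 0 * s
  }
  P <- prod_rate(s, p) / p$lam - s - Cp
  g <- p$k_k * P * Q - p$k_p * s * Q - p$lam * (s + Cp)
  ifelse(P < 0, -(1 + s), g)
}

# Scalar balance for the detailed model: an inner 1-D solve for free Q at
# given s (the PhoQ-P balance), then the phosphotransfer-complex
# consistency as the outer residual.
balance_detailed <- function(s, p) {
  vapply(s, function(si) {
    r <- detailed_inner(si, p)
    if (is.null(r)) -(1 + si) else r$resid
  }, 0)
}

detailed_inner <- function(s, p) {
  f <- prod_rate(s, p)
  Tt <- f / p$lam
  Kt <- (p$k_off_t + p$k_cat_t + p$lam) / p$k_on_t
  Kp <- (p$k_off_p + p$k_cat_p + p$lam) / p$k_on_p
  parts <- function(Q) {                     # vectorized over Q
    Cp <- s * Q / Kp
    Ct <- (s * Q * (p$k_cat_p + p$lam) / Kp + p$lam * s) / p$k_cat_t
    P <- Tt - s - Ct - Cp
    Qs <- Tt - Q - Ct - Cp
    list(P = P, Qs = Qs, Ct = Ct, Cp = Cp)
  }
  qbal <- function(Q) {                      # PhoQ-P balance
    w <- parts(Q)
    p$k_a * Q + p$k_off_t * w$Ct - p$k_on_t * w$P * w$Qs - p$lam * w$Qs
  }
  qg <- c(0, exp(seq(log(Tt) - 26, log(Tt), length.out = 240)))
  rv <- qbal(qg)
  i <- which(diff(sign(rv)) != 0)
  if (!length(i)) return(NULL)
  Q <- uniroot(qbal, c(qg[i[1]], qg[i[1] + 1]),
               f.lower = rv[i[1]], f.upper = rv[i[1] + 1],
               tol = 1e-14)$root
  w <- parts(Q)
  if (w$P < 0 || w$Qs < 0) return(NULL)
  list(resid = w$P * w$Qs / Kt - w$Ct, Q = Q, w = w)
}

balance_fun <- function(params) {
  switch(class(params)[1],
         reduced_params = balance_reduced,
         decoupled_params = balance_decoupled,
         detailed_params = balance_detailed)
}

# Reconstruct the full state vector from a scalar Pstar root.
reconstruct_state <- function(s, params) {
  p <- params
  if (inherits(p, "reduced_params")) {
    Fv <- prod_rate(s, p) / p$lam
    return(c(P = Fv - s, Q = Fv, Pstar = s))
  }
  if (inherits(p, "decoupled_params")) {
    if (is.finite(p$K_d)) {
      Kde <- p$K_d + p$lam / p$k_on_p
      Cp <- p$Q_tot * s / (Kde + s)
    } else Cp <- 0
    return(c(P = prod_rate(s, p) / p$lam - s - Cp, Pstar = s, C_p = Cp))
  }
  r <- detailed_inner(s, p)
  if (is.null(r)) stop("cannot reconstruct detailed state at Pstar = ", s)
  c(P = r$w$P, Pstar = s, Q = r$Q, Qstar = r$w$Qs, C_t = r$w$Ct,
    C_p = r$w$Cp)
}

# Upper bound of the Pstar search window: total protein cannot exceed
# maximal production over dilution.
pstar_upper <- function(params) 1.05 * (params$V_0 + params$V_f) / params$lam

# Polish a bracketed root by secant steps guarded by bisection, to
# relative bracket width ~1e-13 (the residual check is the backstop).
polish_root <- function(g, lo, hi, flo, fhi) {
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)
  for (it in 1:200) {
    if (hi - lo <= 1e-13 * max(abs(hi), 1e-300)) break
    # secant step, alternating with plain bisection to guarantee
    # bracket shrinkage
    mid <- if (it %% 2 == 1 && is.finite(flo) && is.finite(fhi) &&
               fhi != flo) {
      cand <- lo - flo * (hi - lo) / (fhi - flo)
      if (cand <= lo || cand >= hi) (lo + hi) / 2 else cand
    } else (lo + hi) / 2
    # keep strictly inside the bracket
    if (mid <= lo) mid <- lo + (hi - lo) * 1e-3
    if (mid >= hi) mid <- hi - (hi - lo) * 1e-3
    fm <- g(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm }
    else { hi <- mid; fhi <- fm }
  }
  (lo + hi) / 2
}

# Magnitude scale of the fluxes entering the balance at a state, used to
# normalize steady-state residuals (cancellation between large kinase /
# phosphatase fluxes bounds the achievable absolute residual).
flux_scale <- function(params, state) {
  p <- params
  f <- prod_rate(state[["Pstar"]], p)
  lamterm <- p$lam * (1 + sum(state))
  extra <- if (inherits(p, "reduced_params")) {
    p$k_k * state[["P"]] * state[["Q"]] +
      p$k_p * state[["Pstar"]] * state[["Q"]]
  } else if (inherits(p, "decoupled_params")) {
    Q <- max(p$Q_tot - state[["C_p"]], 0)
    bind <- if (is.finite(p$K_d))
      p$k_on_p * state[["Pstar"]] * Q + p$K_d * p$k_on_p * state[["C_p"]]
    else 0
    p$k_k * state[["P"]] * Q + p$k_p * state[["Pstar"]] * Q + bind
  } else {
    p$k_a * state[["Q"]] +
      p$k_on_t * state[["P"]] * state[["Qstar"]] +
      (p$k_off_t + p$k_cat_t) * state[["C_t"]] +
      p$k_on_p * state[["Pstar"]] * state[["Q"]] +
      (p$k_off_p + p$k_cat_p) * state[["C_p"]]
  }
  f + lamterm + extra
}

#' Locate all steady states of a circuit model
#'
#' Reduces the steady-state conditions to a scalar balance equation in
#' the PhoP-P concentration, brackets every sign change on a log-spaced
#' grid over the physically admissible window `[0, (V_0+V_f)/lam]`, and
#' polishes each bracket to a root. Each root is reconstructed to a full
#' state vector, verified against the model right-hand side, and
#' classified stable/unstable by [jacobian_stability()].
#'
#' @param params a `circuit_params` object.
#' @param window optional numeric `c(lo, hi)` Pstar search window;
#'   defaults to the production/dilution bound.
#' @param n_grid number of bracketing grid points (default 4000).
#' @param tol residual tolerance for accepting a root, measured as
#'   `max|rhs| / (lam * (1 + sum(state)))`.
#' @param classify if `TRUE` (default) attach a regime label via
#'   [classify_regime()].
#' @return object of class `steady_state_set`: a list with `states`
#'   (matrix, one row per steady state, ordered by Pstar), `Pstar`,
#'   `stability` (`"stable"`/`"unstable"`), and `regime`.
#' @examples
#' find_steady_states(default_params("T281R"))
#' @export
find_steady_states <- function(params, window = NULL, n_grid = 4000,
                               tol = 1e-8, classify = TRUE) {
  stopifnot(inherits(params, "circuit_params"))
  g <- balance_fun(params)
  hi <- if (is.null(window)) pstar_upper(params) else window[2]
  lo <- if (is.null(window)) 0 else window[1]
  hi <- max(hi, 1e-8)   # degenerate window when production is zero
  grid <- unique(c(lo, exp(seq(log(max(lo, 1e-10)), log(hi),
                               length.out = n_grid)), hi))
  gv <- g(grid, params)
  if (anyNA(gv)) stop("balance equation returned NA; invalid parameters?")
  idx <- which(diff(sign(gv)) != 0 & gv[-length(gv)] != 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- polish_root(function(s) g(s, params), grid[i], grid[i + 1],
                     gv[i], gv[i + 1])
    if (is.na(r))
      stop("root polishing failed in bracket [", grid[i], ", ",
           grid[i + 1], "]")
    roots <- c(roots, r)
  }
  if (any(gv == 0)) roots <- c(roots, grid[gv == 0])
  roots <- sort(unique(roots))
  # drop near-duplicates from adjacent brackets
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) / pmax(roots[-1], 1e-12) > 1e-7)
    roots <- roots[keep]
  }
  if (!length(roots))
    stop("no steady state found in window [", lo, ", ", hi,
         "]; widen the window or refine the grid")
  states <- t(vapply(roots, reconstruct_state, reconstruct_state(roots[1],
                     params), params = params))
  rhs <- rhs_fun(params)
  for (k in seq_along(roots)) {
    resid <- max(abs(rhs(0, states[k, ], NULL)[[1]]))
    if (resid / flux_scale(params, states[k, ]) > tol)
      stop("steady-state residual ", signif(resid, 3),
           " exceeds tolerance at Pstar = ", signif(roots[k], 6))
  }
  stab <- vapply(seq_along(roots), function(k)
    jacobian_stability(params, states[k, ]), "")
  out <- structure(list(states = states, Pstar = roots, stability = stab,
                        regime = NA_character_, params = params),
                   class = "steady_state_set")
  if (classify) out$regime <- classify_regime(out)
  out
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat("<steady_state_set> regime:", x$regime, "\n")
  df <- data.frame(Pstar = signif(x$Pstar, 6), stability = x$stability)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Linear stability of a steady state
#'
#' Classifies a steady state by the eigenvalues of the numerically
#' linearized right-hand side: stable iff every eigenvalue has negative
#' real part. Real parts within `marginal_tol` of zero are reported as
#' `"marginal"`.
#'
#' @param params a `circuit_params` object.
#' @param state a steady state of the corresponding model (checked).
#' @param marginal_tol eigenvalue tie tolerance (default 1e-9).
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
jacobian_stability <- function(params, state, marginal_tol = 1e-9) {
  rhs <- rhs_fun(params)
  fields <- state_fields(params)
  state <- check_state(state, fields)
  r0 <- rhs(0, state, NULL)[[1]]
  if (max(abs(r0)) / (params$lam * (1 + sum(state))) > 1e-6)
    stop("state is not a steady state (|rhs| too large)")
  n <- length(state)
  J <- matrix(0, n, n)
  hs <- pmax(abs(state), 1e-6) * 1e-6
  for (j in seq_len(n)) {
    up <- dn <- state
    up[j] <- state[j] + hs[j]
    dn[j] <- max(state[j] - hs[j], 0)
    J[, j] <- (rhs(0, up, NULL)[[1]] - rhs(0, dn, NULL)[[1]]) /
      (up[j] - dn[j])
  }
  re <- Re(eigen(J, only.values = TRUE)$values)
  scale <- max(abs(re), params$lam)
  if (any(abs(re) < marginal_tol * scale)) return("marginal")
  if (all(re < 0)) "stable" else "unstable"
}

#' Classify the dynamical regime of a steady-state set
#'
#' Two stable states give `"bistable"`. A single stable state is
#' `"monostable_off"` or `"monostable_on"` according to whether its
#' PhoP-P value lies below or above `ref_scale`. Marginal states are
#' excluded from the count.
#'
#' @param sset a `steady_state_set`.
#' @param ref_scale reference PhoP-P scale separating OFF from ON;
#'   defaults to the feedback half-saturation `K_f` (callers that know a
#'   nearby bistable point, e.g. [bifurcation_sweep()], pass the
#'   geometric mean of its OFF/ON branches instead).
#' @return regime label.
#' @export
classify_regime <- function(sset, ref_scale = NULL) {
  stopifnot(inherits(sset, "steady_state_set"))
  if (!length(sset$Pstar)) stop("empty steady-state set")
  ref <- ref_scale %||% sset$params$K_f
  stable <- sset$Pstar[sset$stability == "stable"]
  if (length(stable) > 2)
    stop("more than two stable states: model violation")
  if (length(stable) == 2) return("bistable")
  if (length(stable) == 0) stop("no stable steady state found")
  if (stable < ref) "monostable_off" else "monostable_on"
}

#' Clamp a steady-state value for display
#'
#' Values below `1e-4` are reported as `1e-4` on the logarithmic display
#' scale used by regime maps and branch diagrams.
#'
#' @param value nonnegative numeric (vectorized).
#' @return `pmax(value, 1e-4)`.
#' @export
clamp_for_display <- function(value) {
  if (anyNA(value) || any(value < 0)) stop("value must be nonnegative")
  pmax(value, 1e-4)
}
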