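#' Build a stochastic reaction network from circuit parameters
#'
#' Translates a deterministic parameter set into a discrete reaction
#' network for exact stochastic simulation. Concentrations map to counts
#' through the system-size parameter `Omega` (counts = conc * `Omega`);
#' the autoregulated production propensity uses the promoter form in the
#' PhoP-P *count* with maximal feedback rate `C_P1 = V_f * Omega` and
#' basal rate `C_P2 = V_0 * Omega`. Phosphatase-dead parameter sets
#' (`k_p = 0` or `k_cat_p = 0`) contain no phosphatase-catalysis
#' reaction; the decoupled network's *phoQ* production is a constant-rate
#' reaction independent of PhoP-P.
#'
#' @param params a `circuit_params` object (the variant is implied by its
#'   class and zeroed rates; see [make_variant()]).
#' @param Omega system size converting concentrations to molecule counts
#'   (>= 1; default 100).
#' @param scheme `"reduced"` (3 species; default) or `"detailed"`
#'   (6 species, mirroring [detailed_rhs()]). Reduced and decoupled
#'   parameter sets use their own native schemes.
#' @return object of class `reaction_network`: species names,
#'   stoichiometry matrix (species x reactions), per-reaction propensity
#'   specification, `Omega`, and the originating parameters.
#' @examples
#' net <- build_network(default_params("T281R"), Omega = 100)
#' net$species
#' @export
build_network <- function(params, Omega = 100,
                          scheme = c("reduced", "detailed")) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(Omega) || Omega < 1) stop("Omega must be >= 1")
  scheme <- match.arg(scheme)
  p <- params
  rx <- list()
  add <- function(rx, name, type, rate = 0, i = NA, j = NA, delta) {
    rx[[name]] <- list(type = type, rate = rate, i = i, j = j,
                       delta = delta)
    rx
  }
  hill <- c(p$V_0, p$V_f, p$K_f, p$h)

  if (inherits(p, "decoupled_params")) {
    species <- c("P", "Pstar", "Q", "C_p")
    rx <- add(rx, "prod_P", 3, i = "Pstar", delta = c(P = 1))
    rx <- add(rx, "prod_Q", 0, rate = p$k_cons * p$lam * p$Q_tot * Omega,
              delta = c(Q = 1))
    rx <- add(rx, "kinase", 2, rate = p$k_k / Omega, i = "P", j = "Q",
              delta = c(P = -1, Pstar = 1))
    if (p$k_p > 0)
      rx <- add(rx, "phosphatase", 2, rate = p$k_p / Omega, i = "Pstar",
                j = "Q", delta = c(Pstar = -1, P = 1))
    if (is.finite(p$K_d)) {
      rx <- add(rx, "bind_p", 2, rate = p$k_on_p / Omega, i = "Pstar",
                j = "Q", delta = c(Pstar = -1, Q = -1, C_p = 1))
      rx <- add(rx, "unbind_p", 1, rate = p$k_on_p * p$K_d, i = "C_p",
                delta = c(C_p = -1, Pstar = 1, Q = 1))
    }
  } else if (inherits(p, "detailed_params") && scheme == "detailed") {
    species <- c("P", "Pstar", "Q", "Qstar", "C_t", "C_p")
    rx <- add(rx, "prod", 3, i = "Pstar", delta = c(P = 1, Q = 1))
    rx <- add(rx, "autophos", 1, rate = p$k_a, i = "Q",
              delta = c(Q = -1, Qstar = 1))
    rx <- add(rx, "bind_t", 2, rate = p$k_on_t / Omega, i = "P",
              j = "Qstar", delta = c(P = -1, Qstar = -1, C_t = 1))
    rx <- add(rx, "unbind_t", 1, rate = p$k_off_t, i = "C_t",
              delta = c(C_t = -1, P = 1, Qstar = 1))
    rx <- add(rx, "cat_t", 1, rate = p$k_cat_t, i = "C_t",
              delta = c(C_t = -1, Pstar = 1, Q = 1))
    rx <- add(rx, "bind_p", 2, rate = p$k_on_p / Omega, i = "Pstar",
              j = "Q", delta = c(Pstar = -1, Q = -1, C_p = 1))
    rx <- add(rx, "unbind_p", 1, rate = p$k_off_p, i = "C_p",
              delta = c(C_p = -1, Pstar = 1, Q = 1))
    if (p$k_cat_p > 0)
      rx <- add(rx, "cat_p", 1, rate = p$k_cat_p, i = "C_p",
                delta = c(C_p = -1, P = 1, Q = 1))
  } else {
    # reduced scheme (also the reduced projection of detailed params)
    species <- c("P", "Q", "Pstar")
    rx <- add(rx, "prod", 3, i = "Pstar", delta = c(P = 1, Q = 1))
    rx <- add(rx, "kinase", 2, rate = p$k_k / Omega, i = "P", j = "Q",
              delta = c(P = -1, Pstar = 1))
    if (p$k_p > 0)
      rx <- add(rx, "phosphatase", 2, rate = p$k_p / Omega, i = "Pstar",
                j = "Q", delta = c(Pstar = -1, P = 1))
  }

  nu <- matrix(0L, length(species), length(rx),
               dimnames = list(species, names(rx)))
  for (k in seq_along(rx)) {
    d <- rx[[k]]$delta
    nu[names(d), k] <- as.integer(d)
  }
  structure(list(species = species, nu = nu, reactions = rx,
                 hill = hill, Omega = Omega, params = params,
                 scheme = scheme),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", length(x$species), "species,",
      length(x$reactions), "reactions, Omega =", x$Omega, "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  reactions:", paste(names(x$reactions), collapse = ", "), "\n")
  invisible(x)
}

# Assemble the C++-ready arguments, optionally appending first-order
# dilution reactions (continuous dilution policy).
network_lowlevel <- function(network, dilution = FALSE) {
  rx <- network$reactions
  nu <- network$nu
  if (dilution) {
    lam <- network$params$lam
    for (s in network$species) {
      d <- stats::setNames(-1, s)
      rx[[paste0("dilute_", s)]] <- list(type = 1, rate = lam, i = s,
                                         j = NA, delta = d)
      nu <- cbind(nu, 0L)
      nu[s, ncol(nu)] <- -1L
    }
  }
  idx <- function(s) ifelse(is.na(s), -1L,
                            match(s, network$species) - 1L)
  list(nu = nu,
       rtype = vapply(rx, function(r) as.integer(r$type), 0L),
       rate = vapply(rx, function(r) as.numeric(r$rate), 0),
       ri = vapply(rx, function(r) idx(r$i), 0L),
       rj = vapply(rx, function(r) idx(r$j), 0L),
       hillpar = matrix(rep(network$hill, each = length(rx)),
                        nrow = length(rx)))
}

#' Run one exact stochastic simulation
#'
#' Gillespie direct-method simulation of a [build_network()] network for
#' `n_generations` cell generations of fixed duration `log(2)/lam`.
#' Growth is handled by the division policy: `"division"` (default)
#' partitions every molecule count binomially (p = 1/2) into the
#' followed daughter at each generation boundary; `"dilution"` instead
#' represents growth as continuous first-order loss reactions at rate
#' `lam` (no partitioning noise), which is the policy whose ensemble mean
#' converges exactly to the deterministic limit.
#'
#' @param network a `reaction_network`.
#' @param init named numeric of initial counts (defaults to all zero);
#'   non-integer values are rounded.
#' @param n_generations number of generations to simulate (>= 0).
#' @param seed integer seed (R RNG); identical seed and configuration
#'   give identical results.
#' @param policy `"division"` or `"dilution"`.
#' @param max_steps hard cap on reaction events (default 1e9).
#' @return object of class `ssa_result`: `final` counts, `gen_means`
#'   (per-generation time-averaged counts, generations x species),
#'   `gen_end` (counts at each generation boundary, after division),
#'   `steps`, `seed`, `n_generations`, `policy`.
#' @export
gillespie_run <- function(network, init = NULL, n_generations = 35,
                          seed = NULL, policy = c("division", "dilution"),
                          max_steps = 1e9) {
  stopifnot(inherits(network, "reaction_network"), n_generations >= 0)
  policy <- match.arg(policy)
  x0 <- numeric(length(network$species))
  names(x0) <- network$species
  if (!is.null(init)) {
    if (is.null(names(init))) names(init) <- network$species[seq_along(init)]
    x0[names(init)] <- init
  }
  if (any(x0 < 0)) stop("initial counts must be nonnegative")
  x0 <- round(x0)
  ll <- network_lowlevel(network, dilution = policy == "dilution")
  t_gen <- log(2) / network$params$lam
  res <- with_seed(seed, ssa_run_cpp(ll$nu, ll$rtype, ll$rate, ll$ri,
                                     ll$rj, ll$hillpar, network$Omega,
                                     x0, t_gen, as.integer(n_generations),
                                     policy == "division", max_steps))
  names(res$final) <- network$species
  colnames(res$gen_means) <- colnames(res$gen_end) <- network$species
  structure(c(res, list(seed = seed, n_generations = n_generations,
                        policy = policy, Omega = network$Omega)),
            class = "ssa_result")
}

#' Run an ensemble of independent stochastic simulations
#'
#' @param network a `reaction_network`.
#' @param init initial counts (see [gillespie_run()]).
#' @param n_runs number of independent runs (>= 0).
#' @param base_seed integer; run `k` uses seed `base_seed + k`, so the
#'   whole table is deterministic given `base_seed`.
#' @param ... passed to [gillespie_run()].
#' @return data.frame with one row per run: `run`, `seed`, final counts
#'   (`final_<species>`) and time-averaged counts over the last
#'   generation (`mean_<species>`), plus `n_generations`.
#' @export
run_ensemble <- function(network, init = NULL, n_runs = 1000,
                         base_seed = 1, ...) {
  stopifnot(n_runs >= 0)
  sp <- network$species
  cols <- c("run", "seed", paste0("final_", sp), paste0("mean_", sp),
            "n_generations")
  if (n_runs == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    r <- gillespie_run(network, init = init, seed = base_seed + k, ...)
    last <- if (nrow(r$gen_means)) r$gen_means[nrow(r$gen_means), ]
            else r$final
    rows[[k]] <- c(run = k, seed = base_seed + k, r$final, last,
                   n_generations = r$n_generations)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  out
}

#' Deterministic (large-Omega) limit of a reaction network
#'
#' Maps each reaction propensity to its concentration-space rate law and
#' returns the mass-action rate equations whose steady states are the
#' large-`Omega` limit of the stochastic model. Division partitioning is
#' represented by its mean effect, continuous dilution at rate `lam`.
#'
#' @param network a `reaction_network`.
#' @return list with `rhs` (function of a named concentration vector)
#'   and `func` (deSolve-compatible wrapper).
#' @export
deterministic_limit <- function(network) {
  p <- network$params
  Om <- network$Omega
  sp <- network$species
  rx <- network$reactions
  nu <- network$nu
  rhs <- function(x) {
    x <- check_state(x, sp)
    a <- vapply(rx, function(r) {
      switch(as.character(r$type),
             "0" = r$rate / Om,
             "1" = r$rate * x[[r$i]],
             "2" = r$rate * Om * x[[r$i]] * x[[r$j]],
             "3" = prod_rate(x[[r$i]], p),
             stop("no deterministic limit registered for propensity type ",
                  r$type))
    }, 0)
    drop(nu %*% a) - p$lam * x
  }
  list(rhs = rhs, func = function(t, y, parms) list(rhs(pmax(y, 0))))
}

#' Fraction of primed runs in an endpoint ensemble
#'
#' A run is primed when its mean PhoP-P count over the last generation
#' exceeds `threshold`.
#'
#' @param endpoints an endpoint table from [run_ensemble()].
#' @param threshold priming threshold in counts (> 0). A natural choice
#'   is the geometric mean of the OFF and ON deterministic references.
#' @param species species column to threshold (default `"Pstar"`).
#' @return percent of runs primed (0-100).
#' @export
priming_fraction <- function(endpoints, threshold, species = "Pstar") {
  if (!nrow(endpoints)) stop("empty endpoint table")
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  v <- endpoints[[paste0("mean_", species)]]
  100 * mean(v > threshold)
}

#' Detect ON/OFF switching events in a trajectory
#'
#' Applies a hysteresis band: an ON-to-OFF event is recorded only when
#' the trajectory, having last been at or above `on_threshold`, falls to
#' or below `off_threshold` (and symmetrically for OFF-to-ON). Chatter
#' inside the band produces no events.
#'
#' @param trajectory numeric vector of per-generation PhoP-P counts, or
#'   an `ssa_result` (its `gen_means[, "Pstar"]` is used).
#' @param off_threshold,on_threshold band edges; `off_threshold <
#'   on_threshold` required.
#' @return data.frame with columns `direction` (`"on_to_off"` /
#'   `"off_to_on"`) and `generation` (index at which the crossing
#'   completed); zero rows if no events.
#' @export
detect_switch <- function(trajectory, off_threshold, on_threshold) {
  if (off_threshold >= on_threshold)
    stop("off_threshold must be smaller than on_threshold")
  if (inherits(trajectory, "ssa_result"))
    trajectory <- trajectory$gen_means[, "Pstar"]
  state <- NA_character_
  dirs <- character(0)
  gens <- integer(0)
  for (g in seq_along(trajectory)) {
    v <- trajectory[g]
    region <- if (v >= on_threshold) "ON" else if (v <= off_threshold)
      "OFF" else NA_character_
    if (!is.na(region)) {
      if (!is.na(state) && region != state) {
        dirs <- c(dirs, if (region == "OFF") "on_to_off" else "off_to_on")
        gens <- c(gens, g)
      }
      state <- region
    }
  }
  data.frame(direction = dirs, generation = gens,
             stringsAsFactors = FALSE)
}

#' Classify ensemble endpoints relative to OFF/ON references
#'
#' Each endpoint is `near_off` or `near_on` when its log-distance to
#' that reference, `|log10((n + 1) / (ref + 1))|`, is below `log_tol`
#' decades and smaller than the distance to the other reference;
#' otherwise it is `intermediate`.
#'
#' @param endpoints endpoint table from [run_ensemble()].
#' @param off_ref,on_ref reference counts (from the deterministic-limit
#'   steady states, scaled by `Omega`).
#' @param log_tol half-width of the "near" window in decades (default 1).
#' @param species species column (default `"Pstar"`).
#' @return named numeric: fractions `near_off`, `near_on`,
#'   `intermediate`, summing to 1.
#' @export
bimodality_report <- function(endpoints, off_ref, on_ref, log_tol = 1,
                              species = "Pstar") {
  if (!nrow(endpoints)) stop("empty endpoint table")
  if (off_ref >= on_ref) stop("off_ref must be below on_ref")
  v <- endpoints[[paste0("mean_", species)]]
  d_off <- abs(log10((v + 1) / (off_ref + 1)))
  d_on <- abs(log10((v + 1) / (on_ref + 1)))
  near_off <- d_off < log_tol & d_off < d_on
  near_on <- d_on < log_tol & d_on <= d_off
  c(near_off = mean(near_off), near_on = mean(near_on),
    intermediate = mean(!near_off & !near_on))
}
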