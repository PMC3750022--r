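#' Build a culture phase schedule
#'
#' A schedule is an ordered list of growth phases. Each phase has a
#' duration in generations, a growth rate `lam`, and optional parameter
#' overrides applied for that phase only: either absolute values
#' (`k_k = 0.002`) or multipliers (`k_k_mult = 2`), the latter standing
#' in for environmental inputs such as external magnesium acting on the
#' kinase rate or maximal expression rate.
#'
#' @param ... phases, each a list with elements `generations` (> 0),
#'   optional `lam` (> 0; defaults to the baseline parameter value) and
#'   optional `overrides` (named list).
#' @return object of class `phase_schedule`.
#' @examples
#' sta <- phase_schedule(list(generations = 10),
#'                       list(generations = 10, lam = 0.01),
#'                       list(generations = 10))
#' @export
phase_schedule <- function(...) {
  phases <- list(...)
  if (!length(phases)) stop("schedule needs at least one phase")
  for (ph in phases) {
    if (is.null(ph$generations) || ph$generations <= 0)
      stop("each phase needs generations > 0")
    if (!is.null(ph$lam) && ph$lam <= 0)
      stop("phase growth rate lam must be > 0")
  }
  structure(phases, class = "phase_schedule")
}

apply_overrides <- function(params, lam = NULL, overrides = NULL) {
  p <- unclass(params)
  if (!is.null(lam)) p$lam <- lam
  for (nm in names(overrides)) {
    if (grepl("_mult$", nm)) {
      fld <- sub("_mult$", "", nm)
      if (!fld %in% names(p)) stop("unknown override field: ", fld)
      p[[fld]] <- p[[fld]] * overrides[[nm]]
    } else {
      if (!nm %in% names(p)) stop("unknown override field: ", nm)
      p[[nm]] <- overrides[[nm]]
    }
  }
  validate_params(p, class(params)[1])
}

#' Simulate a culture history and classify the outcome (priming assay)
#'
#' Integrates the deterministic model through a [phase_schedule()]
#' starting from the OFF or ON steady state of the baseline parameters,
#' then classifies the final state against the baseline OFF/ON
#' references by log-proximity. Priming is the deterministic conversion
#' of an OFF start to the ON state, which occurs when some phase carries
#' the system into the monostable-ON regime (e.g. a slow-growth
#' stationary phase) and hysteresis preserves the ON state afterwards.
#'
#' With `engine = "ssa"` an ensemble of stochastic runs is propagated
#' through the schedule instead and the ON fraction is reported.
#'
#' @param params baseline `circuit_params` (typically bistable).
#' @param schedule a [phase_schedule()].
#' @param start `"OFF"`, `"ON"`, or a named state vector.
#' @param engine `"ode"` (default) or `"ssa"`.
#' @param Omega,n_runs,base_seed stochastic-engine settings (ignored for
#'   `"ode"`).
#' @return list with `final_state`, `state` (`"OFF"`/`"ON"`), and
#'   `fraction_on` (0/1 for the ODE engine).
#' @export
priming_assay <- function(params, schedule, start = c("OFF", "ON"),
                          engine = c("ode", "ssa"), Omega = 100,
                          n_runs = 50, base_seed = 1) {
  stopifnot(inherits(schedule, "phase_schedule"))
  engine <- match.arg(engine)
  refs <- off_on_references(params)
  if (is.character(start)) {
    start <- match.arg(start)
    y0 <- refs[[tolower(start)]]
  } else y0 <- check_state(start, state_fields(params))

  classify_end <- function(y) {
    d_off <- abs(log((y[["Pstar"]] + 1e-12) / (refs$off[["Pstar"]] + 1e-12)))
    d_on <- abs(log((y[["Pstar"]] + 1e-12) / (refs$on[["Pstar"]] + 1e-12)))
    if (d_on < d_off) "ON" else "OFF"
  }

  if (engine == "ode") {
    y <- y0
    for (ph in schedule) {
      pp <- apply_overrides(params, lam = ph$lam, overrides = ph$overrides)
      dur <- ph$generations * log(2) / pp$lam
      sol <- deSolve::ode(y = y, times = c(0, dur), func = rhs_fun(pp),
                          parms = NULL, method = "lsoda",
                          rtol = 1e-9, atol = 1e-12)
      y <- pmax(sol[nrow(sol), -1], 0)
      names(y) <- state_fields(params)
    }
    st <- classify_end(y)
    return(list(final_state = y, state = st,
                fraction_on = as.numeric(st == "ON")))
  }

  # stochastic engine: propagate each run's counts through the phases
  counts <- matrix(round(rep(y0 * Omega, each = n_runs)), nrow = n_runs,
                   dimnames = list(NULL, names(y0)))
  for (iph in seq_along(schedule)) {
    ph <- schedule[[iph]]
    pp <- apply_overrides(params, lam = ph$lam, overrides = ph$overrides)
    net <- build_network(pp, Omega = Omega)
    for (k in seq_len(n_runs)) {
      r <- gillespie_run(net, init = counts[k, net$species],
                         n_generations = ph$generations,
                         seed = base_seed + 7919L * iph + k)
      counts[k, net$species] <- r$final
    }
  }
  on <- counts[, "Pstar"] / Omega >
    sqrt(max(refs$off[["Pstar"]], 1e-12) * refs$on[["Pstar"]])
  list(final_state = counts, state = ifelse(mean(on) > 0.5, "ON", "OFF"),
       fraction_on = mean(on))
}

# OFF and ON stable references of a (bistable) baseline parameter set.
off_on_references <- function(params) {
  ss <- find_steady_states(params, classify = FALSE)
  stable <- which(ss$stability == "stable")
  if (length(stable) < 1) stop("baseline has no stable state")
  off <- ss$states[stable[1], ]
  on <- ss$states[stable[length(stable)], ]
  list(off = off, on = on, bistable = length(stable) == 2)
}

#' Induction-hysteresis sweep
#'
#' Emulates the induction experiment on the decoupled circuit: across a
#' monotone induction grid (total PhoQ for the decoupled model, kinase
#' rate for an autoregulated control), stochastic ensembles are started
#' from both an uninduced (OFF-like) and a fully induced (ON-like)
#' state and grown for `n_generations`. For each grid point the median
#' endpoint PhoP-P and its standard error are reported for both starts;
#' absence of hysteresis means the two endpoint summaries agree within
#' sampling error everywhere.
#'
#' @param params a `decoupled_params` (grid applies to `Q_tot`) or
#'   `reduced_params` (grid applies to `k_k`; autoregulated control).
#' @param grid monotone induction grid.
#' @param n_generations generations of growth (default 15).
#' @param n_runs runs per grid point and start (default 30).
#' @param Omega system size (default 100).
#' @param base_seed integer seed.
#' @return data.frame with one row per grid point: medians and standard
#'   errors of endpoint PhoP-P counts for low and high starts, and their
#'   difference in combined SE units (`z`).
#' @export
induction_hysteresis <- function(params, grid, n_generations = 15,
                                 n_runs = 30, Omega = 100,
                                 base_seed = 1) {
  d <- diff(grid)
  if (length(grid) < 2 || !(all(d > 0) || all(d < 0)))
    stop("induction grid must be strictly monotone")
  par_name <- if (inherits(params, "decoupled_params")) "Q_tot" else "k_k"
  # start states: endpoints of the induction axis
  p_hi <- set_param(params, par_name, max(grid))
  refs <- off_on_references(p_hi)
  med_se <- function(v) {
    m <- median(v)
    se <- 1.2533 * stats::sd(v) / sqrt(length(v))  # asymptotic SE of median
    c(m, se)
  }
  out <- lapply(seq_along(grid), function(i) {
    p <- set_param(params, par_name, grid[i])
    net <- build_network(p, Omega = Omega)
    ends <- function(y0, seed0) {
      init <- stats::setNames(numeric(length(net$species)), net$species)
      shared <- intersect(names(y0), net$species)
      init[shared] <- y0[shared]
      if ("Q" %in% net$species && !"Q" %in% names(y0)) {
        cp <- if ("C_p" %in% names(y0)) y0[["C_p"]] else 0
        init["Q"] <- max(p$Q_tot - cp, 0)
      }
      e <- run_ensemble(net, init = round(init * Omega), n_runs = n_runs,
                        base_seed = seed0,
                        n_generations = n_generations)
      e$mean_Pstar
    }
    lo <- ends(c(P = 0, Pstar = 0), base_seed + 1000L * i)
    hi <- ends(refs$on, base_seed + 1000L * i + 500L)
    a <- med_se(lo); b <- med_se(hi)
    data.frame(induction = grid[i], median_low_start = a[1],
               se_low_start = a[2], median_high_start = b[1],
               se_high_start = b[2],
               z = abs(a[1] - b[1]) / sqrt(a[2]^2 + b[2]^2 + 1e-12))
  })
  out <- do.call(rbind, out)
  names(out)[1] <- par_name
  out
}

#' Configuration for a serial-dilution lineage experiment
#'
#' Encodes the daily protocol: a large dilution (binomial bottleneck of
#' `n_b` founder cells), regrowth for `log2(dilution)` generations with
#' per-generation stochastic OFF/ON switching, then a stationary-phase
#' block in which ON cells survive with relative probability `s_on`
#' (their competitive disadvantage in saturated culture).
#'
#' @param n_days number of serial-dilution days (default 5).
#' @param dilution daily dilution factor (default 1e6).
#' @param n_b founder cells per bottleneck (default 2000).
#' @param generations_per_day generations of regrowth; defaults to
#'   `round(log2(dilution))` (about 20 for a million-fold dilution).
#' @param p_on_off,p_off_on per-generation switching probabilities.
#' @param s_on relative stationary-phase survival of ON cells, in (0, 1].
#' @param n_replicates independent lineages (default 7).
#' @param start `"ON"` or `"OFF"` founding colony state, or a numeric
#'   starting ON fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `lineage_config`.
#' @export
lineage_config <- function(n_days = 5, dilution = 1e6, n_b = 2000,
                           generations_per_day = NULL, p_on_off = 1e-4,
                           p_off_on = 0, s_on = 0.5, n_replicates = 7,
                           start = c("ON", "OFF"), seed = 1) {
  if (is.numeric(start)) {
    if (start < 0 || start > 1) stop("numeric start must be in [0, 1]")
  } else start <- match.arg(start)
  gpd <- generations_per_day %||% round(generations_from_dilution(dilution))
  stopifnot(n_days >= 1, n_b >= 1, gpd >= 1, n_replicates >= 1)
  if (p_on_off < 0 || p_on_off > 1 || p_off_on < 0 || p_off_on > 1)
    stop("switching probabilities must be in [0, 1]")
  if (s_on <= 0 || s_on > 1) stop("s_on must be in (0, 1]")
  structure(list(n_days = n_days, dilution = dilution, n_b = n_b,
                 generations_per_day = gpd, p_on_off = p_on_off,
                 p_off_on = p_off_on, s_on = s_on,
                 n_replicates = n_replicates, start = start, seed = seed),
            class = "lineage_config")
}

# Binomial draw that falls back to a Poisson/normal approximation for
# population sizes beyond integer range.
big_rbinom <- function(n, p) {
  if (p <= 0 || n <= 0) return(0)
  if (p >= 1) return(n)
  if (n <= 1e8) return(rbinom(1, n, p))
  mu <- n * p
  if (mu < 1e8) return(rpois(1, mu))
  max(0, round(rnorm(1, mu, sqrt(n * p * (1 - p)))))
}

#' Simulate serial-dilution lineages with stationary-phase selection
#'
#' A two-state (OFF/ON) population process following the daily protocol
#' in a [lineage_config()]: each day starts with a binomial bottleneck
#' of `n_b` founders drawn from the previous day's composition, grows
#' for `generations_per_day` doublings with stochastic per-generation
#' switching, then passes through stationary phase where ON cells
#' survive with probability `s_on`. Deterministic given the seed.
#'
#' @param config a [lineage_config()].
#' @return object of class `lineage_trace`: data.frame with one row per
#'   replicate per day (`replicate`, `day`, `frac_on`, `frac_off`,
#'   `pop_size`, `extinct`).
#' @examples
#' tr <- lineage_simulation(lineage_config(p_on_off = 1e-4, s_on = 0.5))
#' aggregate(frac_on ~ day, tr, mean)
#' @export
lineage_simulation <- function(config) {
  stopifnot(inherits(config, "lineage_config"))
  cfg <- config
  with_seed(cfg$seed, {
    rows <- list()
    for (rep in seq_len(cfg$n_replicates)) {
      frac_on <- if (is.numeric(cfg$start)) cfg$start
                 else as.numeric(cfg$start == "ON")
      for (day in seq_len(cfg$n_days)) {
        on <- rbinom(1, cfg$n_b, frac_on)
        off <- cfg$n_b - on
        extinct <- FALSE
        for (g in seq_len(cfg$generations_per_day)) {
          on <- 2 * on
          off <- 2 * off
          sw_on_off <- big_rbinom(on, cfg$p_on_off)
          sw_off_on <- big_rbinom(off, cfg$p_off_on)
          on <- on - sw_on_off + sw_off_on
          off <- off + sw_on_off - sw_off_on
        }
        on <- big_rbinom(on, cfg$s_on)       # stationary-phase selection
        total <- on + off
        if (total <= 0) {
          extinct <- TRUE
          frac_on <- NA_real_
        } else frac_on <- on / total
        rows[[length(rows) + 1L]] <-
          data.frame(replicate = rep, day = day, frac_on = frac_on,
                     frac_off = 1 - frac_on, pop_size = total,
                     extinct = extinct)
        if (extinct) break
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("lineage_trace", "data.frame")
    out
  })
}
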