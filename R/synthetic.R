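#' Parameters for the synthetic single-cell generator
#'
#' Describes the statistical structure of the two-state single-cell
#' measurements the quantification functions assume: a two-component
#' log-scale mixture of reporter ratios with a configurable fold
#' separation between OFF and ON medians (default 60-fold), a
#' state-independent constitutive normalizer channel, and
#' state-dependent cell width (ON cells narrower than OFF cells).
#'
#' @param n number of cells (>= 0).
#' @param fraction_on latent ON fraction in `[0, 1]`.
#' @param off_ratio_median median YFP/CFP of OFF cells (default 1).
#' @param fold fold separation between ON and OFF median ratios
#'   (default 60, > 1).
#' @param cv log-scale coefficient of variation per channel
#'   (multiplicative measurement noise; default 0.3).
#' @param cfp_median median of the constitutive channel (default 100).
#' @param width_off_mean,width_on_mean mean cell width per state, um;
#'   ON must be below OFF (defaults 1.0 and 0.75).
#' @param width_sd width standard deviation (default 0.08 um).
#' @param yfp_ceiling optional saturation ceiling on YFP (reporter
#'   saturation in the ON state); `Inf` disables (default).
#' @param seed integer seed.
#' @return object of class `cell_gen_params`.
#' @export
cell_gen_params <- function(n, fraction_on = 0.5, off_ratio_median = 1,
                            fold = 60, cv = 0.3, cfp_median = 100,
                            width_off_mean = 1.0, width_on_mean = 0.75,
                            width_sd = 0.08, yfp_ceiling = Inf,
                            seed = 1) {
  stopifnot(n >= 0, fraction_on >= 0, fraction_on <= 1, fold > 1,
            off_ratio_median > 0, cv > 0, cfp_median > 0,
            width_sd > 0, width_on_mean > 0)
  if (width_on_mean >= width_off_mean)
    stop("ON cells must have smaller mean width than OFF cells")
  structure(list(n = n, fraction_on = fraction_on,
                 off_ratio_median = off_ratio_median, fold = fold,
                 cv = cv, cfp_median = cfp_median,
                 width_off_mean = width_off_mean,
                 width_on_mean = width_on_mean, width_sd = width_sd,
                 yfp_ceiling = yfp_ceiling, seed = seed),
            class = "cell_gen_params")
}

#' Generate a synthetic single-cell measurement table
#'
#' Draws per-cell YFP, CFP and width values with the two-state
#' structure described by [cell_gen_params()]: latent OFF/ON labels are
#' Bernoulli(`fraction_on`); CFP is lognormal around `cfp_median`
#' independent of state; YFP is lognormal with state-dependent median
#' (`off_ratio_median * cfp_median`, times `fold` for ON cells); width
#' is normal, truncated at zero, with a lower mean in the ON state.
#' Deterministic given the seed.
#'
#' @param params a [cell_gen_params()] object.
#' @return a cell table: data.frame with columns `cell_id`, `yfp`,
#'   `cfp`, `width`, `label` (latent ground truth).
#' @examples
#' cells <- simulate_cells(cell_gen_params(n = 500, seed = 42))
#' classify_cells(cells)
#' @export
simulate_cells <- function(params) {
  stopifnot(inherits(params, "cell_gen_params"))
  p <- params
  if (p$n == 0)
    return(data.frame(cell_id = integer(0), yfp = numeric(0),
                      cfp = numeric(0), width = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  with_seed(p$seed, {
    on <- runif(p$n) < p$fraction_on
    sdlog <- sqrt(log(1 + p$cv^2))
    cfp <- rlnorm(p$n, log(p$cfp_median), sdlog)
    yfp_median <- p$off_ratio_median * p$cfp_median *
      ifelse(on, p$fold, 1)
    yfp <- pmin(rlnorm(p$n, log(yfp_median), sdlog), p$yfp_ceiling)
    mu_w <- ifelse(on, p$width_on_mean, p$width_off_mean)
    width <- rnorm(p$n, mu_w, p$width_sd)
    while (any(width <= 0))
      width[width <= 0] <- rnorm(sum(width <= 0), mu_w[width <= 0],
                                 p$width_sd)
    data.frame(cell_id = seq_len(p$n), yfp = yfp, cfp = cfp,
               width = width, label = ifelse(on, "ON", "OFF"),
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic competition counts with known ground truth
#'
#' Constructs plate counts consistent with a requested competitive
#' ratio for a competition started with an exact 1:1 resistant:sensitive
#' mixture. The sensitive survival fraction implied by `true_cr` is
#' `sigma = g * (2 - true_cr) / true_cr` for resistant growth factor
#' `g`; `true_cr = 2` therefore eliminates the sensitive population.
#' With `noise = TRUE` each plate count is drawn Poisson around its
#' expectation; with `noise = FALSE` the exact expected counts are
#' returned (non-integer values allowed).
#'
#' @param true_cr target competitive ratio, in `(0, 2]`.
#' @param L0 initial total count (default 400).
#' @param g resistant growth factor over the competition (default 1).
#' @param noise draw Poisson plating noise? (default `TRUE`).
#' @param seed integer seed.
#' @return a [competition_counts()] object with attribute `truth`.
#' @export
simulate_competition <- function(true_cr, L0 = 400, g = 1, noise = TRUE,
                                 seed = 1) {
  if (true_cr <= 0 || true_cr > 2)
    stop("true_cr must be in (0, 2] for a 1:1 competition design")
  if (L0 <= 0 || g <= 0) stop("base counts and growth factor must be > 0")
  C0 <- L0 / 2                       # exact 1:1 mixture
  sigma <- g * (2 - true_cr) / true_cr
  C10 <- g * C0
  L10 <- C10 + sigma * (L0 - C0)
  counts <- c(C0 = C0, L0 = L0, C10 = C10, L10 = L10)
  if (noise)
    counts <- with_seed(seed, vapply(counts, function(m)
      rpois(1, m) + 0.0, 0))
  if (counts[["C10"]] > counts[["L10"]]) counts[["L10"]] <- counts[["C10"]]
  if (counts[["C0"]] > counts[["L0"]]) counts[["L0"]] <- counts[["C0"]]
  out <- competition_counts(counts[["C0"]], counts[["L0"]],
                            counts[["C10"]], counts[["L10"]])
  attr(out, "truth") <- list(true_cr = true_cr, sigma = sigma, g = g)
  out
}

#' Generate a synthetic switching trajectory with known events
#'
#' Piecewise-constant latent levels with multiplicative noise, for
#' exercising [detect_switch()] against ground truth.
#'
#' @param levels latent level per segment (positive).
#' @param segment_lengths generations per segment (same length as
#'   `levels`).
#' @param noise_cv multiplicative noise CV (0 disables noise).
#' @param seed integer seed.
#' @return list with `trajectory` (numeric, one value per generation)
#'   and `events` (ground-truth data.frame of direction/generation for
#'   each level change).
#' @export
simulate_switch_trajectory <- function(levels, segment_lengths,
                                       noise_cv = 0, seed = 1) {
  stopifnot(length(levels) == length(segment_lengths),
            all(levels >= 0), all(segment_lengths >= 1))
  latent <- rep(levels, segment_lengths)
  traj <- if (noise_cv > 0)
    with_seed(seed, latent * rlnorm(length(latent),
                                    -log(1 + noise_cv^2) / 2,
                                    sqrt(log(1 + noise_cv^2))))
  else latent
  cuts <- cumsum(segment_lengths)
  ev <- NULL
  if (length(levels) > 1) {
    d <- diff(levels)
    ev <- data.frame(
      direction = ifelse(d < 0, "on_to_off", "off_to_on"),
      generation = cuts[-length(cuts)] + 1L,
      stringsAsFactors = FALSE)[d != 0, , drop = FALSE]
  }
  list(trajectory = traj,
       events = ev %||% data.frame(direction = character(0),
                                   generation = integer(0)))
}
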