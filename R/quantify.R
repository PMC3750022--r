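#' Competition plate counts
#'
#' Colony counts from a two-strain competition: `C0`, `C10` on selective
#' (chloramphenicol) plates and `L0`, `L10` on plain plates at 0 and 10
#' hours. The resistant subpopulation is a subset of the total, so
#' `C0 <= L0` and `C10 <= L10`. Counts may be non-integer (plate counts
#' back-scaled by dilution); invariants are checked to a rounding
#' tolerance of 1e-6.
#'
#' @param C0,L0,C10,L10 nonnegative counts.
#' @return object of class `competition_counts`.
#' @export
competition_counts <- function(C0, L0, C10, L10) {
  v <- c(C0 = C0, L0 = L0, C10 = C10, L10 = L10)
  if (anyNA(v) || any(v < 0)) stop("counts must be nonnegative")
  if (C0 > L0 + 1e-6 || C10 > L10 + 1e-6)
    stop("resistant counts cannot exceed totals (C <= L)")
  structure(as.list(v), class = "competition_counts")
}

#' Competitive ratio (CR)
#'
#' `CR = (C10 * L0) / (C0 * L10)`: the fold change of the resistant
#' fraction over the competition. For a competition initiated with an
#' exact 1:1 resistant:sensitive mixture CR is bounded above by 2
#' (attained when the sensitive population is eliminated), and CR = 1
#' is neutral. CR is invariant under common rescaling of all four
#' counts.
#'
#' @param counts a [competition_counts()] object.
#' @return the competitive ratio.
#' @examples
#' competitive_ratio(competition_counts(100, 200, 100, 200))  # neutral: 1
#' competitive_ratio(competition_counts(100, 200, 150, 150))  # bound: 2
#' @export
competitive_ratio <- function(counts) {
  stopifnot(inherits(counts, "competition_counts"))
  if (counts$C0 <= 0 || counts$L10 <= 0)
    stop("competitive_ratio needs C0 > 0 and L10 > 0")
  (counts$C10 * counts$L0) / (counts$C0 * counts$L10)
}

#' Competitive index (CI)
#'
#' The quotient of final and initial ratios of the two competing
#' subpopulations, `CI = (C10 / (L10 - C10)) / (C0 / (L0 - C0))`.
#' Unlike [competitive_ratio()], CI is unbounded, and it cannot be
#' computed when the sensitive population falls below detection
#' (`L10 = C10`), which raises an error rather than returning a number.
#'
#' @param counts a [competition_counts()] object.
#' @return the competitive index.
#' @export
competitive_index <- function(counts) {
  stopifnot(inherits(counts, "competition_counts"))
  S0 <- counts$L0 - counts$C0
  S10 <- counts$L10 - counts$C10
  if (S0 <= 1e-6) stop("no sensitive cells at start (L0 = C0)")
  if (S10 <= 1e-6)
    stop("sensitive population below detection: CI cannot be computed")
  if (counts$C0 <= 0) stop("competitive_index needs C0 > 0")
  (counts$C10 / S10) / (counts$C0 / S0)
}

#' Probability that an inoculum contains a minority cell
#'
#' For a transfer of `n` cells from a culture with minority fraction
#' `f`, the binomial-sampling probability that at least one minority
#' cell is present: `1 - (1 - f)^n`. Nondecreasing in both arguments.
#'
#' @param n cells transferred (nonnegative integer).
#' @param f minority fraction in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @examples
#' inoculum_presence_probability(2000, 0.001)  # ~0.86, "about 90%"
#' @export
inoculum_presence_probability <- function(n, f) {
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  1 - (1 - f)^n
}

#' Generations of regrowth implied by a dilution factor
#'
#' A culture diluted `d`-fold must double `log2(d)` times to regrow to
#' its previous density; a million-fold daily dilution therefore implies
#' about 20 generations of exponential growth per day.
#'
#' @param d dilution factor (>= 1).
#' @return number of doublings, `log2(d)`.
#' @export
generations_from_dilution <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 1))
    stop("dilution factor must be >= 1")
  log2(d)
}

#' Estimate the OFF/ON threshold of a log-ratio distribution
#'
#' Splits the per-cell log(YFP/CFP) values into two components with a
#' 1-D two-means partition and returns the geometric midpoint between
#' the component centres on the ratio scale.
#'
#' @param ratio positive per-cell YFP/CFP ratios (length >= 2).
#' @return threshold on the ratio scale.
#' @export
estimate_ratio_threshold <- function(ratio) {
  if (length(ratio) < 2 || any(ratio <= 0)) stop("need >= 2 positive ratios")
  lx <- log(ratio)
  if (diff(range(lx)) == 0) return(exp(lx[1]))
  km <- kmeans(lx, centers = range(lx), iter.max = 50)
  exp(mean(km$centers))
}

#' Classify cells as OFF or ON from reporter ratios
#'
#' Per-cell classification of the PhoP-P state by the ratio of the
#' PhoP-P-responsive reporter (YFP) to the constitutive normalizer
#' (CFP). With `threshold = NULL` the cutoff is estimated from the
#' two-component structure of the log-ratio distribution
#' ([estimate_ratio_threshold()]); a fixed threshold can be supplied
#' instead. Because the threshold acts on the ratio, the percent ON is
#' invariant under common multiplicative rescaling of both channels
#' (illumination invariance).
#'
#' @param cells a cell table (data.frame with positive `yfp` and `cfp`
#'   columns; see [simulate_cells()]).
#' @param threshold ratio cutoff, or `NULL` to estimate it.
#' @return list of class `cell_classification`: `labels`
#'   (`"OFF"`/`"ON"`), `percent_on`, `threshold`, `n`.
#' @export
classify_cells <- function(cells, threshold = NULL) {
  if (!nrow(cells)) stop("empty cell table")
  if (!all(c("yfp", "cfp") %in% names(cells)))
    stop("cell table needs yfp and cfp columns")
  if (any(cells$cfp <= 0)) stop("CFP values must be positive")
  if (any(cells$yfp <= 0)) stop("YFP values must be positive")
  ratio <- cells$yfp / cells$cfp
  thr <- threshold %||% estimate_ratio_threshold(ratio)
  labels <- ifelse(ratio > thr, "ON", "OFF")
  structure(list(labels = labels, percent_on = 100 * mean(labels == "ON"),
                 threshold = thr, n = length(labels)),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("<cell_classification> n = %d, %.1f%% ON (threshold %.4g)\n",
              x$n, x$percent_on, x$threshold))
  invisible(x)
}

#' Median and geometric mean of the reporter ratio
#'
#' @param cells cell table with positive `yfp` and `cfp` columns.
#' @return named numeric: `median` and `geometric_mean` of the per-cell
#'   YFP/CFP ratio.
#' @export
summarize_ratios <- function(cells) {
  if (!nrow(cells)) stop("empty cell table")
  if (any(cells$cfp <= 0) || any(cells$yfp <= 0))
    stop("channels must be positive")
  r <- cells$yfp / cells$cfp
  c(median = median(r), geometric_mean = exp(mean(log(r))))
}
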