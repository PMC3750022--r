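#' Circuit parameter sets
#'
#' Constructors for the three deterministic circuit models of the
#' autoregulated two-component system: the reduced three-species model
#' (PhoP, PhoQ, PhoP-P), the detailed six-species model (adding PhoQ-P and
#' the phosphotransfer and phosphatase complexes), and the decoupled
#' variant in which *phoQ* expression is held constitutive at a fixed
#' total concentration `Q_tot` while *phoP* remains autoregulated.
#'
#' All quantities are dimensionless model units: concentrations scaled to
#' the feedback saturation scale, time scaled so that typical growth rates
#' are of order `lam = 0.02`. Rate fields carry 1/time (or 1/(conc*time))
#' dimension and are the ones affected by [rescale_time()].
#'
#' @param k_k kinase rate constant (1/(conc*time)); flux is `k_k * P * Q`.
#' @param k_p phosphatase rate constant (1/(conc*time)); flux is
#'   `k_p * Pstar * Q`. Zero for phosphatase-dead variants.
#' @param V_0 constitutive (basal) protein production rate (conc/time).
#' @param V_f maximal feedback production rate (conc/time).
#' @param K_f feedback half-saturation concentration (conc), must be > 0.
#' @param h Hill coefficient of the feedback (dimensionless, >= 1).
#'   Default 1: autoregulation of both operon partners supplies the
#'   effective cooperativity, no binding cooperativity is assumed.
#' @param lam specific growth rate lambda (1/time); growth-mediated
#'   dilution is the only loss term for the stable proteins.
#' @return An object of class `reduced_params`, `detailed_params` or
#'   `decoupled_params` (all inheriting `circuit_params`): a named list of
#'   validated numeric fields.
#' @seealso [make_variant()], [rescale_time()], [default_params()]
#' @examples
#' p <- reduced_params(k_k = 0.001, k_p = 0, V_0 = 0.005, V_f = 1,
#'                     K_f = 5, lam = 0.02)
#' find_steady_states(p)
#' @export
reduced_params <- function(k_k, k_p, V_0, V_f, K_f, h = 1, lam = 0.02) {
  p <- list(k_k = k_k, k_p = k_p, V_0 = V_0, V_f = V_f, K_f = K_f,
            h = h, lam = lam)
  validate_params(p, "reduced_params")
}

#' @rdname reduced_params
#' @param k_a PhoQ autophosphorylation rate (1/time).
#' @param k_on_t,k_off_t,k_cat_t phosphotransfer complex binding, unbinding
#'   and catalysis rates; the effective kinase constant in the
#'   quasi-steady-state limit is `k_cat_t / K_t` with
#'   `K_t = (k_off_t + k_cat_t + lam) / k_on_t`.
#' @param k_on_p,k_off_p,k_cat_p phosphatase complex rates; `K_d =
#'   k_off_p / k_on_p` is the dissociation constant of the
#'   PhoP-P:PhoQ complex.
#' @export
detailed_params <- function(k_k = NULL, k_p = NULL, V_0, V_f, K_f, h = 1,
                            lam = 0.02, k_a, k_on_t, k_off_t, k_cat_t,
                            k_on_p, k_off_p, k_cat_p) {
  K_t <- (k_off_t + k_cat_t + lam) / k_on_t
  K_p <- (k_off_p + k_cat_p + lam) / k_on_p
  p <- list(k_k = k_k %||% (k_cat_t / K_t), k_p = k_p %||% (k_cat_p / K_p),
            V_0 = V_0, V_f = V_f, K_f = K_f, h = h, lam = lam,
            k_a = k_a, k_on_t = k_on_t, k_off_t = k_off_t,
            k_cat_t = k_cat_t, k_on_p = k_on_p, k_off_p = k_off_p,
            k_cat_p = k_cat_p, K_d = k_off_p / k_on_p)
  validate_params(p, "detailed_params")
}

#' @rdname reduced_params
#' @param Q_tot total PhoQ concentration held by constitutive expression
#'   (conc, >= 0).
#' @param k_cons constitutive phoQ production scale (dimensionless,
#'   default 1).
#' @param K_d dissociation constant of the PhoP-P:PhoQ (phosphatase
#'   intermediate) complex. `Inf` (default) disables complex formation;
#'   finite small values sequester PhoQ and PhoP-P into a catalytically
#'   inert complex.
#' @param k_on_p association rate used to resolve `K_d` into binding
#'   kinetics for time-dependent integration (ignored when `K_d = Inf`).
#' @export
decoupled_params <- function(k_k, k_p = 0, V_0, V_f, K_f, h = 1,
                             lam = 0.02, Q_tot, k_cons = 1, K_d = Inf,
                             k_on_p = 10) {
  p <- list(k_k = k_k, k_p = k_p, V_0 = V_0, V_f = V_f, K_f = K_f,
            h = h, lam = lam, Q_tot = Q_tot, k_cons = k_cons,
            K_d = K_d, k_on_p = k_on_p)
  validate_params(p, "decoupled_params")
}

validate_params <- function(p, class) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, TRUE)
  if (!all(num))
    stop("all parameter fields must be single numeric values: ",
         paste(names(p)[!num], collapse = ", "))
  bad <- vapply(p, function(x) is.na(x) || x < 0, TRUE)
  if (any(bad))
    stop("negative or missing parameter value: ",
         paste(names(p)[bad], collapse = ", "))
  if (p$lam <= 0) stop("lam must be > 0")
  if (p$h < 1) stop("h must be >= 1")
  if (p$K_f <= 0) stop("K_f must be > 0")
  structure(p, class = c(class, "circuit_params"))
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flds <- vapply(x, format, "", digits = 6)
  cat(paste0("  ", format(names(flds)), " = ", flds, collapse = "\n"), "\n")
  invisible(x)
}

#' Circuit variant tags
#'
#' The closed set of circuit variants: `wild_type` (bifunctional kinase /
#' phosphatase), `T281R` (phosphatase-dead, kinase-impaired point mutant),
#' `T281R_dP2` (the mutant with the constitutive operon promoter deleted)
#' and `decoupled` (*phoQ* expression removed from PhoP-P feedback
#' control).
#'
#' @return Character vector of valid variant tags.
#' @export
variant_tags <- function() c("wild_type", "T281R", "T281R_dP2", "decoupled")

#' Derive a circuit variant from a base parameter set
#'
#' Applies the parameter transformations that represent each strain:
#' the T281R substitution abolishes phosphatase activity and leaves a
#' poorer kinase (`k_p = 0`, kinase scaled by `kappa < 1`); the
#' additional P2 promoter deletion reduces basal transcription
#' (`V_0` scaled by `delta`, not to zero -- residual basal transcription
#' remains); decoupling removes the feedback from *phoQ* production only,
#' clamping total PhoQ at `Q_tot`.
#'
#' @param base a `reduced_params` or `detailed_params` object.
#' @param tag one of [variant_tags()].
#' @param kappa kinase-deficit factor for T281R (default 0.1). For the
#'   detailed model it scales `k_cat_t` (catalytic efficiency of
#'   phosphotransfer).
#' @param delta basal-transcription deficit factor for the P2 deletion
#'   (default 0.1).
#' @param Q_tot,K_d,k_on_p passed to [decoupled_params()] when
#'   `tag = "decoupled"`.
#' @return a `circuit_params` object of the appropriate class.
#' @examples
#' t281r <- make_variant(default_params("wild_type"), "T281R")
#' @export
make_variant <- function(base, tag, kappa = 0.1, delta = 0.1,
                         Q_tot = NULL, K_d = Inf, k_on_p = 10) {
  stopifnot(inherits(base, "circuit_params"))
  tag <- match.arg(tag, variant_tags())
  if (kappa <= 0 || kappa >= 1) stop("kappa must be in (0, 1)")
  detailed <- inherits(base, "detailed_params")
  if (tag == "wild_type") return(base)
  if (tag == "decoupled") {
    if (is.null(Q_tot)) stop("decoupled variant requires Q_tot")
    return(decoupled_params(k_k = base$k_k, k_p = 0, V_0 = base$V_0,
                            V_f = base$V_f, K_f = base$K_f, h = base$h,
                            lam = base$lam, Q_tot = Q_tot, K_d = K_d,
                            k_on_p = k_on_p))
  }
  p <- unclass(base)
  if (detailed) {
    p$k_cat_p <- 0
    p$k_cat_t <- kappa * p$k_cat_t
    p$k_k <- p$k_p <- NULL
    p <- do.call(detailed_params, p[setdiff(names(p), "K_d")])
  } else {
    p$k_p <- 0
    p$k_k <- kappa * p$k_k
  }
  if (tag == "T281R_dP2") p$V_0 <- delta * p$V_0
  if (detailed) p else do.call(reduced_params, p[names(formals(reduced_params))])
}

#' Rescale the kinetic time base of a parameter set
#'
#' Multiplies every rate-dimension field by `c`, leaving concentrations
#' (`K_f`, `K_d`, `Q_tot`) and dimensionless fields untouched. The
#' steady-state set is invariant under this transformation; only time
#' scales change, so a reduction in growth rate is equivalent to an
#' upscaling of all kinetic parameters.
#'
#' @param params a `circuit_params` object.
#' @param c positive rescaling factor.
#' @return parameters of the same class with rates multiplied by `c`.
#' @export
rescale_time <- function(params, c) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0)
    stop("rescaling factor c must be a positive number")
  rate_fields <- c("k_k", "k_p", "V_0", "V_f", "lam", "k_a",
                   "k_on_t", "k_off_t", "k_cat_t",
                   "k_on_p", "k_off_p", "k_cat_p")
  out <- unclass(params)
  for (f in intersect(rate_fields, names(out))) out[[f]] <- c * out[[f]]
  if (!is.null(out$K_d) && inherits(params, "detailed_params"))
    out$K_d <- out$k_off_p / out$k_on_p
  structure(out, class = class(params))
}

#' Calibrated default parameter sets
#'
#' Reads the calibrated dimensionless parameter sets shipped with the
#' package (plain-text YAML under `inst/extdata/params/`). The base set
#' was located by bistability scans so that the T281R variant at
#' `lam = 0.02` sits inside its bistable window, the wild-type is
#' monostable everywhere, and the decoupled variant is monostable unless
#' `K_d` is small.
#'
#' @param variant one of [variant_tags()].
#' @param model `"reduced"` or `"detailed"`.
#' @param ... passed to [make_variant()] (e.g. `Q_tot`, `K_d` for the
#'   decoupled variant).
#' @return a `circuit_params` object.
#' @examples
#' default_params("T281R")
#' @export
default_params <- function(variant = "T281R",
                           model = c("reduced", "detailed"), ...) {
  variant <- match.arg(variant, variant_tags())
  model <- match.arg(model)
  cfg_file <- system.file("extdata", "params",
                          paste0("base_", model, ".yaml"),
                          package = "phoswitch", mustWork = TRUE)
  cfg <- yaml::read_yaml(cfg_file)
  ctor <- if (model == "reduced") reduced_params else detailed_params
  base <- do.call(ctor, cfg)
  if (variant == "decoupled") {
    dfile <- system.file("extdata", "params", "decoupled.yaml",
                         package = "phoswitch", mustWork = TRUE)
    dcfg <- yaml::read_yaml(dfile)
    extra <- list(...)
    dcfg[names(extra)] <- extra
    return(do.call(decoupled_params, dcfg))
  }
  make_variant(base, variant, ...)
}
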