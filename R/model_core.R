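#' Autoregulated promoter activity
#'
#' Production rate of the *phoPQ* operon as a function of the
#' phosphorylated response-regulator concentration: a basal term plus a
#' saturating PhoP-P-activated term,
#' `V_0 + V_f * Pstar^h / (K_f^h + Pstar^h)`.
#' The value is bounded in `[V_0, V_0 + V_f]` and monotone nondecreasing
#' in `Pstar`.
#'
#' @param Pstar PhoP-P concentration (vectorized, >= 0).
#' @param V_0 basal production rate.
#' @param V_f maximal feedback production rate.
#' @param K_f half-saturation concentration (> 0).
#' @param h Hill coefficient (>= 1).
#' @return production rate (conc/time), same length as `Pstar`.
#' @export
promoter_activity <- function(Pstar, V_0, V_f, K_f, h = 1) {
  if (any(c(Pstar, V_0, V_f, K_f, h) < 0) || anyNA(c(V_0, V_f, K_f, h)))
    stop("promoter_activity: arguments must be nonnegative")
  if (K_f <= 0) stop("promoter_activity: K_f must be > 0")
  x <- (Pstar / K_f)^h
  V_0 + V_f * x / (1 + x)
}

prod_rate <- function(Pstar, p) {
  promoter_activity(Pstar, p$V_0, p$V_f, p$K_f, p$h)
}

#' Time derivatives of the reduced three-species model
#'
#' The reduced model tracks PhoP (`P`), PhoQ (`Q`) and PhoP-P (`Pstar`).
#' P and Q are co-produced from the single autoregulated operon at rate
#' [promoter_activity()]; the kinase flux is `k_k * P * Q`, the
#' phosphatase flux `k_p * Pstar * Q`, and every species is diluted at
#' the growth rate `lam` (growth-mediated dilution is the only loss term
#' for these stable proteins).
#'
#' @param state named numeric `(P, Q, Pstar)`, all >= 0.
#' @param params a [reduced_params()] object.
#' @return named numeric vector of derivatives `(P, Q, Pstar)`.
#' @export
reduced_rhs <- function(state, params) {
  stopifnot(inherits(params, "reduced_params"))
  st <- check_state(state, c("P", "Q", "Pstar"))
  f <- prod_rate(st[["Pstar"]], params)
  kin <- params$k_k * st[["P"]] * st[["Q"]]
  pho <- params$k_p * st[["Pstar"]] * st[["Q"]]
  c(P = f - kin + pho - params$lam * st[["P"]],
    Q = f - params$lam * st[["Q"]],
    Pstar = kin - pho - params$lam * st[["Pstar"]])
}

#' Time derivatives of the detailed six-species model
#'
#' Adds the phosphorylated kinase and the two enzymatic intermediates to
#' the reduced scheme:
#' \itemize{
#'   \item autophosphorylation `Q -> Qstar` at `k_a`,
#'   \item phosphotransfer `P + Qstar <-> C_t -> Pstar + Q`
#'     (`k_on_t`, `k_off_t`, `k_cat_t`),
#'   \item phosphatase `Pstar + Q <-> C_p -> P + Q`
#'     (`k_on_p`, `k_off_p`, `k_cat_p`),
#'   \item co-production of P and Q at [promoter_activity()] and dilution
#'     of every species, complexes included, at `lam`.
#' }
#'
#' @param state named numeric `(P, Pstar, Q, Qstar, C_t, C_p)`.
#' @param params a [detailed_params()] object.
#' @return named numeric vector of derivatives.
#' @export
detailed_rhs <- function(state, params) {
  stopifnot(inherits(params, "detailed_params"))
  st <- check_state(state, c("P", "Pstar", "Q", "Qstar", "C_t", "C_p"))
  p <- params
  f <- prod_rate(st[["Pstar"]], p)
  bt <- p$k_on_t * st[["P"]] * st[["Qstar"]]      # transfer-complex binding
  bp <- p$k_on_p * st[["Pstar"]] * st[["Q"]]      # phosphatase-complex binding
  c(P = f + p$k_cat_p * st[["C_p"]] + p$k_off_t * st[["C_t"]] - bt -
        p$lam * st[["P"]],
    Pstar = p$k_cat_t * st[["C_t"]] + p$k_off_p * st[["C_p"]] - bp -
        p$lam * st[["Pstar"]],
    Q = f + p$k_cat_t * st[["C_t"]] +
        (p$k_off_p + p$k_cat_p) * st[["C_p"]] - p$k_a * st[["Q"]] - bp -
        p$lam * st[["Q"]],
    Qstar = p$k_a * st[["Q"]] + p$k_off_t * st[["C_t"]] - bt -
        p$lam * st[["Qstar"]],
    C_t = bt - (p$k_off_t + p$k_cat_t + p$lam) * st[["C_t"]],
    C_p = bp - (p$k_off_p + p$k_cat_p + p$lam) * st[["C_p"]])
}

#' Time derivatives of the decoupled-variant model
#'
#' *phoP* stays under feedback control while the PhoQ pool is clamped:
#' free PhoQ is `Q_tot - C_p`, where `C_p` is the catalytically inert
#' PhoP-P:PhoQ complex formed when `K_d` is finite (binding at `k_on_p`,
#' unbinding at `K_d * k_on_p`). With `K_d = Inf` no complex forms and
#' `Q = Q_tot` throughout.
#'
#' @param state named numeric `(P, Pstar, C_p)`; `C_p` must not exceed
#'   `Q_tot`.
#' @param params a [decoupled_params()] object.
#' @return named numeric vector of derivatives `(P, Pstar, C_p)`.
#' @export
decoupled_rhs <- function(state, params) {
  stopifnot(inherits(params, "decoupled_params"))
  st <- check_state(state, c("P", "Pstar", "C_p"))
  p <- params
  if (p$Q_tot < 0) stop("Q_tot must be nonnegative")
  Q <- max(p$Q_tot - st[["C_p"]], 0)
  f <- prod_rate(st[["Pstar"]], p)
  kin <- p$k_k * st[["P"]] * Q
  pho <- p$k_p * st[["Pstar"]] * Q
  if (is.finite(p$K_d)) {
    bon <- p$k_on_p * st[["Pstar"]] * Q
    boff <- p$K_d * p$k_on_p * st[["C_p"]]
  } else bon <- boff <- 0
  c(P = f - kin + pho - p$lam * st[["P"]],
    Pstar = kin - pho - bon + boff - p$lam * st[["Pstar"]],
    C_p = bon - boff - p$lam * st[["C_p"]])
}

check_state <- function(state, fields) {
  if (is.null(names(state)) || !all(fields %in% names(state))) {
    if (length(state) == length(fields)) names(state) <- fields
    else stop("state must have fields ", paste(fields, collapse = ", "))
  }
  if (anyNA(state) || any(state < 0)) stop("state values must be nonnegative")
  state[fields]
}

# deSolve-compatible wrapper for any of the model rhs functions.
rhs_fun <- function(params) {
  rhs <- switch(class(params)[1],
                reduced_params = reduced_rhs,
                detailed_params = detailed_rhs,
                decoupled_params = decoupled_rhs,
                stop("unknown parameter class"))
  function(t, y, parms) list(rhs(pmax(y, 0), params))
}

state_fields <- function(params) {
  switch(class(params)[1],
         reduced_params = c("P", "Q", "Pstar"),
         detailed_params = c("P", "Pstar", "Q", "Qstar", "C_t", "C_p"),
         decoupled_params = c("P", "Pstar", "C_p"))
}
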