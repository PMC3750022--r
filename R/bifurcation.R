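#' Replace one field of a parameter set (revalidating invariants)
#'
#' @param params a `circuit_params` object.
#' @param name field name (must exist in `params`).
#' @param value replacement value.
#' @return parameters of the same class.
#' @export
set_param <- function(params, name, value) {
  if (!name %in% names(params)) stop("unknown sweep parameter: ", name)
  p <- unclass(params)
  p[[name]] <- value
  validate_params(p, class(params)[1])
}

#' One-dimensional bifurcation sweep
#'
#' Computes the steady-state set along a monotone grid of one parameter,
#' labels the regime at each grid point, and localizes the fold
#' (saddle-node) points where the number of steady states changes by
#' bisection on the sweep parameter.
#'
#' Regime labels use the reference scale the branch diagram itself
#' provides: at each grid point the OFF/ON separatrix scale is the
#' geometric mean of the low and high stable branches at the nearest
#' bistable grid point, falling back to `K_f` when the sweep contains no
#' bistable window.
#'
#' @param params a `circuit_params` object.
#' @param par_name name of the parameter to sweep (e.g. `"k_k"`,
#'   `"k_p"`, `"V_0"`, `"lam"`, `"Q_tot"`).
#' @param grid strictly monotone numeric vector of parameter values.
#' @param fold_tol relative bisection tolerance for fold localization
#'   (default 1e-6).
#' @param ... passed to [find_steady_states()].
#' @return object of class `branch_table`: list with `param`, `grid`,
#'   `sets` (list of `steady_state_set`), `folds` (numeric), and `table`,
#'   a data.frame with one row per grid point (parameter value, root
#'   count, low/mid/high branch Pstar values, regime).
#' @examples
#' bt <- bifurcation_sweep(default_params("T281R"), "k_k",
#'                         10^seq(-5, -1, length.out = 25))
#' table(bt$table$regime)
#' @export
bifurcation_sweep <- function(params, par_name, grid, fold_tol = 1e-6,
                              ...) {
  d <- diff(grid)
  if (length(grid) < 2 || !(all(d > 0) || all(d < 0)))
    stop("grid must be strictly monotone")
  sets <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sets[[i]] <- tryCatch(
      find_steady_states(set_param(params, par_name, grid[i]),
                         classify = FALSE, ...),
      error = function(e)
        stop("steady-state solve failed at ", par_name, " = ", grid[i],
             ": ", conditionMessage(e)))
  }
  nst <- vapply(sets, function(s) sum(s$stability == "stable"), 0L)
  # reference scale: geometric mean of OFF/ON branches at nearest
  # bistable grid point
  bi <- which(nst == 2)
  ref_for <- function(i) {
    if (!length(bi)) return(params$K_f)
    j <- bi[which.min(abs(bi - i))]
    st <- sets[[j]]$Pstar[sets[[j]]$stability == "stable"]
    sqrt(max(st[1], 1e-300) * st[2])
  }
  regimes <- vapply(seq_along(sets), function(i)
    classify_regime(sets[[i]], ref_scale = ref_for(i)), "")
  nroot <- vapply(sets, function(s) length(s$Pstar), 0L)
  branch <- function(s, which) {
    st <- s$Pstar
    if (which == "low") return(st[1])
    if (which == "high") return(if (length(st) > 1) st[length(st)] else NA_real_)
    if (length(st) == 3) st[2] else NA_real_
  }
  tab <- data.frame(
    value = grid, n_roots = nroot, n_stable = nst,
    Pstar_low = vapply(sets, branch, 0, which = "low"),
    Pstar_mid = vapply(sets, branch, 0, which = "mid"),
    Pstar_high = vapply(sets, branch, 0, which = "high"),
    regime = regimes, stringsAsFactors = FALSE)
  names(tab)[1] <- par_name
  folds <- locate_folds(params, par_name, grid, nroot, fold_tol, ...)
  structure(list(param = par_name, grid = grid, sets = sets,
                 folds = folds, table = tab, params = params),
            class = "branch_table")
}

#' @export
print.branch_table <- function(x, ...) {
  cat("<branch_table> sweep of", x$param, "over", length(x$grid),
      "points\n")
  cat("  regimes:", paste(rle(x$table$regime)$values, collapse = " -> "),
      "\n")
  if (length(x$folds))
    cat("  folds at", paste(signif(x$folds, 6), collapse = ", "), "\n")
  invisible(x)
}

# Bisect on the sweep parameter between grid cells where the root count
# changes, to the requested relative tolerance.
locate_folds <- function(params, par_name, grid, nroot, fold_tol = 1e-6,
                         ...) {
  nr_at <- function(v)
    length(find_steady_states(set_param(params, par_name, v),
                              classify = FALSE, ...)$Pstar)
  folds <- numeric(0)
  for (i in which(diff(nroot) != 0)) {
    lo <- grid[i]; hi <- grid[i + 1]
    nlo <- nroot[i]
    while (abs(hi - lo) > fold_tol * max(abs(lo), abs(hi))) {
      mid <- if (lo > 0 && hi > 0) sqrt(lo * hi) else (lo + hi) / 2
      if (nr_at(mid) == nlo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  folds
}

#' Two-dimensional bistability scan
#'
#' Evaluates the steady-state set over the outer product of two monotone
#' parameter grids and reports, per cell, the regime label and a display
#' value: the stable PhoP-P level for monostable cells (clamped below at
#' `1e-4` via [clamp_for_display()]), `NA` for bistable cells (plotted
#' black in the style of the regime maps).
#'
#' @param params a `circuit_params` object.
#' @param x_name,x_grid,y_name,y_grid the two swept parameters and their
#'   monotone grids. `lam` stays fixed at its value in `params`.
#' @param ... passed to [find_steady_states()].
#' @return object of class `regime_map`: list with `x`, `y` (names),
#'   `table`, a data.frame with columns (x value, y value, n_roots,
#'   n_stable, regime, display).
#' @examples
#' rm2 <- bistability_scan(default_params("T281R"), "k_p",
#'                         10^seq(-4, 0, length.out = 8), "V_f",
#'                         10^seq(-1, 1, length.out = 8), n_grid = 1500)
#' @export
bistability_scan <- function(params, x_name, x_grid, y_name, y_grid,
                             ...) {
  for (g in list(x_grid, y_grid)) {
    d <- diff(g)
    if (length(g) < 2 || !(all(d > 0) || all(d < 0)))
      stop("scan grids must be strictly monotone")
  }
  cells <- expand.grid(x = x_grid, y = y_grid, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  nroot <- nst <- integer(n)
  disp <- numeric(n)
  regime <- character(n)
  for (i in seq_len(n)) {
    p <- set_param(set_param(params, x_name, cells$x[i]),
                   y_name, cells$y[i])
    s <- find_steady_states(p, classify = FALSE, ...)
    nroot[i] <- length(s$Pstar)
    stable <- s$Pstar[s$stability == "stable"]
    nst[i] <- length(stable)
    if (nst[i] == 2) {
      regime[i] <- "bistable"
      disp[i] <- NA_real_
    } else {
      regime[i] <- classify_regime(s, ref_scale = params$K_f)
      disp[i] <- clamp_for_display(stable[1])
    }
  }
  tab <- data.frame(x = cells$x, y = cells$y, n_roots = nroot,
                    n_stable = nst, regime = regime, display = disp,
                    stringsAsFactors = FALSE)
  names(tab)[1:2] <- c(x_name, y_name)
  structure(list(x = x_name, y = y_name, table = tab, params = params),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat("<regime_map>", x$x, "x", x$y, ":",
      sum(x$table$regime == "bistable"), "bistable /",
      nrow(x$table), "cells\n")
  invisible(x)
}
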