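# Configuration, table I/O and run manifests.
#
# Configs are plain-text YAML. Every run_command() invocation writes its
# outputs atomically (tempfile + rename) together with a JSON manifest
# recording the config snapshot, seed, package version and output list,
# which suffices to re-run the command bit-identically.

config_schema <- c("model", "variant", "params", "steady", "sweep",
                   "scan2d", "ssa", "protocol", "lineage", "quantify",
                   "synth", "seed")

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, rejects unknown top-level keys, and
#' validates any circuit parameters against the type invariants by
#' constructing them.
#'
#' @param path path to a YAML config file.
#' @return validated configuration list of class `phoswitch_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), config_schema)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$model <- cfg$model %||% "reduced"
  if (!cfg$model %in% c("reduced", "detailed", "decoupled"))
    stop("invalid model: ", cfg$model)
  if (!is.null(cfg$variant) && !cfg$variant %in% variant_tags())
    stop("invalid variant: ", cfg$variant)
  if (!is.null(cfg$params)) config_params(cfg)   # validates, errors name field
  structure(cfg, class = c("phoswitch_config", "list"))
}

# Resolve the circuit parameters a config describes.
config_params <- function(cfg) {
  ctor <- switch(cfg$model, reduced = reduced_params,
                 detailed = detailed_params, decoupled = decoupled_params)
  p <- if (!is.null(cfg$params)) {
    bad <- setdiff(names(cfg$params), names(formals(ctor)))
    if (length(bad))
      stop("unknown parameter field for ", cfg$model, " model: ",
           paste(bad, collapse = ", "))
    tryCatch(do.call(ctor, cfg$params),
             error = function(e) stop("invalid params: ",
                                      conditionMessage(e)))
  } else default_params("wild_type",
                        if (cfg$model == "detailed") "detailed" else "reduced")
  if (!is.null(cfg$variant) && cfg$variant != "wild_type" &&
      !inherits(p, "decoupled_params"))
    p <- make_variant(p, cfg$variant)
  p
}

#' Write a delimited table atomically
#'
#' @param x data.frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.csv(x, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write a cell table
#'
#' Cell tables are CSV with header columns `cell_id`, `yfp`, `cfp`,
#' `width`, `label`.
#'
#' @param path file path.
#' @return data.frame (for the reader).
#' @export
read_cell_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "yfp", "cfp", "width")
  if (!all(need %in% names(x)))
    stop("cell table must have columns ", paste(need, collapse = ", "))
  x
}

#' @rdname read_cell_table
#' @param cells cell table to write.
#' @export
write_cell_table <- function(cells, path) write_table(cells, path)

write_manifest <- function(out_dir, command, cfg, seed, files) {
  man <- list(command = command, config = unclass(cfg), seed = seed,
              package = "phoswitch",
              version = as.character(packageVersion("phoswitch")),
              outputs = basename(files),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  path
}

#' Execute an analysis subcommand
#'
#' Dispatches one of the pipeline subcommands on a validated
#' configuration, writes the resulting tables (atomically) into
#' `out_dir`, and records a JSON run manifest tying the outputs to the
#' config snapshot and seed.
#'
#' Subcommands: `steady` (steady states and regime), `sweep` (1-D
#' bifurcation sweep), `scan2d` (2-D bistability map), `ssa` (stochastic
#' ensemble endpoints), `protocol` (phase-schedule priming assay),
#' `lineage` (serial-dilution lineage simulation), `quantify` (classify
#' and summarize a cell table), `synth` (generate a synthetic cell
#' table with its ground-truth sidecar).
#'
#' @param command subcommand name.
#' @param config a `phoswitch_config` (or path to one).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding `config$seed`.
#' @return character vector of files written (invisibly), manifest last.
#' @export
run_command <- function(command, config, out_dir = ".", seed = NULL) {
  cmds <- c("steady", "sweep", "scan2d", "ssa", "protocol", "lineage",
            "quantify", "synth")
  if (!is.character(command) || !command %in% cmds)
    stop("unknown subcommand '", command, "'; usage: one of ",
         paste(cmds, collapse = ", "))
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "phoswitch_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed %||% 1L
  opts <- config[[command]] %||% list()
  out <- file.path(out_dir, paste0(command, ".csv"))
  files <- out

  if (command == "steady") {
    ss <- find_steady_states(config_params(config))
    tab <- data.frame(Pstar = ss$Pstar, stability = ss$stability,
                      regime = ss$regime)
    write_table(cbind(tab, as.data.frame(ss$states)), out)
  } else if (command == "sweep") {
    p <- config_params(config)
    grid <- seq_grid(opts)
    bt <- bifurcation_sweep(p, opts$param %||% "k_k", grid)
    write_table(bt$table, out)
    if (length(bt$folds)) {
      ff <- file.path(out_dir, "sweep_folds.csv")
      write_table(data.frame(fold = bt$folds), ff)
      files <- c(files, ff)
    }
  } else if (command == "scan2d") {
    p <- config_params(config)
    rmap <- bistability_scan(p, opts$x %||% "k_p", seq_grid(opts$x_grid),
                             opts$y %||% "V_f", seq_grid(opts$y_grid),
                             n_grid = opts$n_grid %||% 2000)
    write_table(rmap$table, out)
  } else if (command == "ssa") {
    p <- config_params(config)
    net <- build_network(p, Omega = opts$Omega %||% 100)
    ends <- run_ensemble(net, init = unlist(opts$init),
                         n_runs = opts$n_runs %||% 100,
                         base_seed = seed,
                         n_generations = opts$n_generations %||% 35)
    write_table(ends, out)
  } else if (command == "protocol") {
    p <- config_params(config)
    phases <- lapply(opts$phases %||% list(list(generations = 20)),
                     identity)
    res <- priming_assay(p, do.call(phase_schedule, phases),
                         start = opts$start %||% "OFF")
    write_table(data.frame(state = res$state,
                           fraction_on = res$fraction_on,
                           t(res$final_state)), out)
  } else if (command == "lineage") {
    cfg_args <- opts
    cfg_args$seed <- seed
    tr <- lineage_simulation(do.call(lineage_config, cfg_args))
    write_table(tr, out)
  } else if (command == "quantify") {
    cells <- read_cell_table(opts$input %||%
                               stop("quantify needs an input path"))
    cl <- classify_cells(cells, threshold = opts$threshold)
    sm <- summarize_ratios(cells)
    write_table(data.frame(n = cl$n, percent_on = cl$percent_on,
                           threshold = cl$threshold,
                           median_ratio = sm[["median"]],
                           geometric_mean_ratio = sm[["geometric_mean"]]),
                out)
  } else if (command == "synth") {
    gen_args <- opts
    gen_args$seed <- seed
    cells <- simulate_cells(do.call(cell_gen_params, gen_args))
    out <- file.path(out_dir, "cells.csv")
    write_cell_table(cells, out)
    gt <- file.path(out_dir, "cells_truth.csv")
    write_table(data.frame(
      n = nrow(cells),
      fraction_on = mean(cells$label == "ON"),
      fold = gen_args$fold %||% 60, seed = seed), gt)
    files <- c(out, gt)
  }
  man <- write_manifest(out_dir, command, config, seed, files)
  invisible(c(files, man))
}

seq_grid <- function(spec) {
  if (is.null(spec)) stop("grid specification missing")
  if (is.numeric(spec) && length(spec) > 1) return(spec)
  if (!is.null(spec$grid)) return(unlist(spec$grid))
  if (!is.null(spec$from)) {
    n <- spec$n %||% 25
    if (isTRUE(spec$log))
      return(10^seq(log10(spec$from), log10(spec$to), length.out = n))
    return(seq(spec$from, spec$to, length.out = n))
  }
  stop("grid specification needs 'grid' or 'from'/'to'")
}
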