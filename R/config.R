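config_fields <- function() {
  c("preset", "strategy", "seed",
    "region_f", "region_r", "grid_spacing",
    "hidden_layers", "width",
    "weights",
    "adam_iters", "adam_lr", "lbfgs_iters",
    "target_nodes", "newton_tol", "max_newton",
    "c_frac", "threshold", "max_iters",
    "rho", "mu")
}

#' Experiment configuration
#'
#' All knobs of a surrogate-training experiment. Two presets exist:
#' \code{"paper_full"} — the full-scale configuration (13 x 13 grid at
#' spacing 1/3, 4 x 80 network, 20000 Adam + up to 50000 L-BFGS iterations
#' per training, ~1000-node meshes, full data retention c = 1) — and
#' \code{"mini"} — a desk-scale configuration for verification and testing
#' (5 x 5 grid, 2 x 32 network, 2000 Adam + 500 L-BFGS iterations,
#' ~300-node meshes, c = 0.25 data retention).
#'
#' @param preset \code{"paper_full"} or \code{"mini"}.
#' @param ... any field to override (see \code{vastra:::config_fields}).
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(preset = c("mini", "paper_full"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset, strategy = "active", seed = 1L,
    region_f = c(-2, 2), region_r = c(-2, 2),
    weights = c(alpha_u = 1, alpha_ns = 1e6, alpha_p = 1e2, alpha_bc = 1e6),
    adam_lr = 1e-4, newton_tol = 1e-10, max_newton = 25,
    rho = 0.00106, mu = 0.004
  )
  # the residual-loss termination threshold is an absolute operating
  # criterion; at mini scale (fewer evaluation nodes, smaller network) the
  # map lives orders of magnitude below the full-scale threshold, so the
  # mini preset is iteration-budget-limited rather than threshold-limited
  scale <- if (preset == "paper_full") {
    list(grid_spacing = 1 / 3, hidden_layers = 4L, width = 80L,
         adam_iters = 20000L, lbfgs_iters = 50000L,
         target_nodes = 1000L, c_frac = 1, max_iters = 164L,
         threshold = 100)
  } else {
    list(grid_spacing = 1, hidden_layers = 2L, width = 32L,
         adam_iters = 2000L, lbfgs_iters = 500L,
         target_nodes = 300L, c_frac = 0.25, max_iters = 20L,
         threshold = 1e-6)
  }
  cfg <- utils::modifyList(c(base, scale), list(...))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  # canonical types, so configurations compare equal after a YAML round trip
  if (is.list(cfg$weights)) cfg$weights <- unlist(cfg$weights)
  for (k in intersect(names(cfg),
                      c("seed", "hidden_layers", "width", "adam_iters",
                        "lbfgs_iters", "target_nodes", "max_newton",
                        "max_iters")))
    if (is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1 && is.finite(cfg[[k]]))
      cfg[[k]] <- as.integer(cfg[[k]])
  for (k in intersect(names(cfg), c("region_f", "region_r")))
    cfg[[k]] <- as.numeric(cfg[[k]])
  unknown <- setdiff(names(cfg), config_fields())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(config_fields(), names(cfg))
  if (length(missing))
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  num1 <- function(key, lo = -Inf, hi = Inf) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < lo || v > hi)
      stop("configuration key '", key, "' must be a scalar in [", lo, ", ", hi, "]")
  }
  if (!cfg$strategy %in% c("active", "random", "uniform"))
    stop("strategy must be one of active, random, uniform")
  if (!cfg$preset %in% c("paper_full", "mini"))
    stop("preset must be paper_full or mini")
  for (k in c("region_f", "region_r"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 2 || cfg[[k]][1] >= cfg[[k]][2])
      stop("configuration key '", k, "' must be an increasing range")
  if (!is.numeric(cfg$weights) || length(cfg$weights) != 4 || any(cfg$weights < 0))
    stop("weights must be four non-negative numbers")
  num1("grid_spacing", 1e-12); num1("seed")
  num1("hidden_layers", 1); num1("width", 1)
  num1("adam_iters", 0); num1("adam_lr", 1e-12); num1("lbfgs_iters", 0)
  num1("target_nodes", 50); num1("newton_tol", 1e-16); num1("max_newton", 1)
  num1("c_frac", 1e-6, 1); num1("threshold", 1e-12); num1("max_iters", 0)
  num1("rho", 1e-12); num1("mu", 1e-12)
  cfg$seed <- as.integer(cfg$seed)
  cfg$region <- list(f = as.numeric(cfg$region_f), r = as.numeric(cfg$region_r))
  structure(cfg, class = "experiment_config")
}

#' @exportS3Method base::print
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment config (%s, %s): grid spacing %g, net %dx%d, Adam %d @ %g + L-BFGS %d, mesh ~%d, c = %g, seed %d\n",
              x$preset, x$strategy, x$grid_spacing, x$hidden_layers, x$width,
              x$adam_iters, x$adam_lr, x$lbfgs_iters, x$target_nodes,
              x$c_frac, x$seed))
  invisible(x)
}

#' Load / save an experiment configuration
#'
#' Plain-YAML persistence with a strict schema: unknown keys are rejected
#' with an itemised message, and a loaded configuration always
#' round-trips (\code{load_config(save_config(cfg)) == cfg}).
#'
#' @param path YAML file path.
#' @return \code{load_config} returns an \code{experiment_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a YAML mapping")
  raw$region <- NULL  # derived field
  validate_config(raw)
}

#' @rdname load_config
#' @param cfg an \code{experiment_config}.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- unclass(cfg)
  out$region <- NULL
  out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a fully-provenanced experiment
#'
#' Wraps \code{\link{run_ala}} with persistence: the configuration, the
#' per-iteration residual maps, loss components and selections, the final
#' network checkpoint, the final evaluation report (when references are
#' available) and a machine-readable run summary are all written under the
#' output directory, so every reported number is recomputable from the
#' stored configuration and seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param out_dir output directory (created; must not already contain a run).
#' @param references optional list of reference FEM solutions (one per grid
#'   row) enabling error reports.
#' @param fem_cache optional environment for oracle reuse across runs.
#' @return the \code{ala_run}, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config, out_dir, references = NULL,
                           fem_cache = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (file.exists(file.path(out_dir, "summary.json")))
    stop("output directory already holds a run: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))
  run <- run_ala(config, references = references, fem_cache = fem_cache)
  grid <- run$state$grid
  for (k in seq_along(run$history)) {
    rec <- run$history[[k]]
    it_dir <- file.path(out_dir, sprintf("iteration_%03d", rec$iteration))
    dir.create(it_dir, showWarnings = FALSE)
    utils::write.csv(
      data.frame(index = seq_len(nrow(grid$points)), grid$points,
                 l_ns = rec$residual_map,
                 sampled = seq_len(nrow(grid$points)) %in% rec$sampled),
      file.path(it_dir, "residual_map.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(t(rec$loss)),
                     file.path(it_dir, "loss.csv"), row.names = FALSE)
    if (!is.null(rec$reports))
      utils::write.csv(rec$reports, file.path(it_dir, "report.csv"),
                       row.names = FALSE)
  }
  save_pinn(run$pinn, file.path(out_dir, "checkpoint.json"))
  summary <- list(
    strategy = config$strategy, seed = config$seed,
    iterations = length(run$history) - 1L,
    sampled = run$state$sampled,
    selected = vapply(run$history, function(r) r$selected, integer(1)),
    termination = attr(run$history, "termination"),
    final_loss = as.list(run$history[[length(run$history)]]$loss),
    final_E = run$history[[length(run$history)]]$E
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run)
}

#' Compare sampling strategies over repeated seeds
#'
#' Runs the loop once per (strategy, seed) pair on an otherwise identical
#' configuration and tabulates the total error E against iteration.
#' Reference FEM solutions (and the oracle cache) are shared across runs,
#' since the ground truth does not depend on the strategy or seed.
#'
#' @param config base \code{\link{experiment_config}} (its strategy field
#'   is overridden per run).
#' @param strategies character vector of strategies to compare.
#' @param seeds integer vector of experiment seeds.
#' @param references list of reference FEM solutions, one per grid row
#'   (computed on demand if omitted).
#' @param max_iters optional cap on iterations for every run.
#' @return list with \code{runs} (data.frame: strategy, seed, iteration,
#'   E, max_residual) and \code{summary} (mean and sd of E per strategy
#'   and iteration).
#' @export
compare_strategies <- function(config, strategies = c("active", "random"),
                               seeds = 1:5, references = NULL,
                               max_iters = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(max_iters)) config$max_iters <- max_iters
  grid <- build_grid(config$region, config$grid_spacing)
  props <- fluid_properties(config$rho, config$mu)
  fem_cache <- new.env(parent = emptyenv())
  if (is.null(references))
    references <- grid_references(config, grid, props, fem_cache)
  rows <- list(); run_list <- list()
  for (strategy in strategies) for (seed in seeds) {
    cfg <- config
    cfg$strategy <- strategy
    cfg$seed <- as.integer(seed)
    run <- run_ala(cfg, references = references, fem_cache = fem_cache)
    run_list[[paste(strategy, seed, sep = "_")]] <- run
    for (rec in run$history) {
      unsampled <- setdiff(seq_len(nrow(grid$points)), rec$sampled)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strategy, seed = seed, iteration = rec$iteration,
        E = rec$E,
        E_unsampled = sum(rec$reports$sq_total[unsampled]),
        max_residual = max(rec$residual_map)
      )
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs[c("iteration", "strategy")]),
    function(d) data.frame(strategy = d$strategy[1], iteration = d$iteration[1],
                           n = nrow(d), mean_E = mean(d$E), sd_E = stats::sd(d$E),
                           mean_E_unsampled = mean(d$E_unsampled))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$strategy, summary$iteration), ]
  list(runs = runs, summary = summary, details = run_list)
}

# reference (ground-truth) solutions at every grid point
grid_references <- function(config, grid, props, fem_cache) {
  mesh_cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(grid$points)), function(i) {
    theta <- as.list(grid$points[i, ])
    mesh <- get_cached_mesh(theta$r, config$target_nodes, mesh_cache)
    fem_oracle_solve(mesh, theta, props, config, fem_cache)
  })
}
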