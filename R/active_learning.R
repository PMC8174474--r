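#' Active-learning state
#'
#' Book-keeping for the sampling loop over the parameter grid G: which grid
#' points have oracle (FEM) data, the latest momentum-residual map over G,
#' the iteration counter, the termination threshold and the strategy.
#'
#' @param grid a \code{\link{build_grid}} result.
#' @param strategy \code{"active"}, \code{"random"} or \code{"uniform"}.
#' @param threshold positive termination threshold on max residual loss.
#' @param seed experiment seed (recorded; the caller seeds the RNG).
#' @return object of class \code{ala_state}.
#' @export
new_ala_state <- function(grid, strategy = c("active", "random", "uniform"),
                          threshold = 100, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "parameter_grid"), threshold > 0)
  sub_idx <- integer(0)
  if (strategy == "uniform") {
    sub <- uniform_subgrid(grid$region, step = 1)
    sub_idx <- match_grid_points(grid, sub)
    if (anyNA(sub_idx))
      stop("uniform sub-grid is not a subset of the parameter grid")
  }
  structure(
    list(grid = grid, strategy = strategy, threshold = threshold,
         seed = as.integer(seed), sampled = integer(0),
         residual_map = rep(NA_real_, nrow(grid$points)),
         iteration = 0L, subgrid_idx = sub_idx),
    class = "ala_state"
  )
}

# row-major indices of given (f, r) points within the grid
match_grid_points <- function(grid, pts) {
  key <- function(f, r) paste(signif(f, 10), signif(r, 10))
  match(key(pts$f, pts$r), key(grid$points$f, grid$points$r))
}

#' @exportS3Method base::print
print.ala_state <- function(x, ...) {
  cat(sprintf("ALA state (%s): iteration %d, %d / %d grid points sampled\n",
              x$strategy, x$iteration, length(x$sampled), nrow(x$grid$points)))
  if (!anyNA(x$residual_map))
    cat(sprintf("  residual map: max %.4g at index %d\n",
                max(x$residual_map), which.max(x$residual_map)))
  invisible(x)
}

#' Momentum-residual acquisition map over the parameter grid
#'
#' Evaluates the residual loss L_NS of the current surrogate at every point
#' of G, sampled or not. The spatial evaluation points for a parameter
#' point are the vertex nodes of a geometry-only mesh for its shape (no
#' FEM solve is performed).
#'
#' @param pinn a \code{pinn}.
#' @param grid a \code{parameter_grid}.
#' @param props \code{\link{fluid_properties}}.
#' @param target_nodes mesh size for the evaluation meshes.
#' @param mesh_cache optional environment caching meshes by shape r.
#' @return numeric vector, one non-negative L_NS value per grid point in
#'   row-major order.
#' @export
acquisition_map <- function(pinn, grid, props = fluid_properties(),
                            target_nodes = 1000, mesh_cache = NULL) {
  pts <- grid$points
  vapply(seq_len(nrow(pts)), function(i) {
    mesh <- get_cached_mesh(pts$r[i], target_nodes, mesh_cache)
    nodes <- mesh$p1$nodes
    rs <- ns_residual(pinn, nodes[, 1], nodes[, 2], pts$f[i], pts$r[i], props)
    sum(rs[, 1]^2 + rs[, 2]^2)
  }, numeric(1))
}

get_cached_mesh <- function(r, target_nodes, cache = NULL) {
  if (is.null(cache)) return(generate_mesh(tube_geometry(r), target_nodes))
  key <- sprintf("%.12g_%d", r, as.integer(target_nodes))
  if (is.null(cache[[key]]))
    cache[[key]] <- generate_mesh(tube_geometry(r), target_nodes)
  cache[[key]]
}

unsampled_indices <- function(state) {
  setdiff(seq_len(nrow(state$grid$points)), state$sampled)
}

#' Select the next parameter point (active strategy)
#'
#' The unsampled grid point with the largest residual-map value; ties are
#' broken towards the lowest row-major index.
#'
#' @param state an \code{ala_state} with a current residual map.
#' @return grid index (row-major).
#' @export
select_next_active <- function(state) {
  cand <- unsampled_indices(state)
  if (!length(cand)) stop("all grid points already sampled")
  if (anyNA(state$residual_map[cand])) stop("residual map not current")
  cand[which.max(state$residual_map[cand])]
}

#' Select the next parameter point (random baseline)
#'
#' Uniform draw over the unsampled grid points, using the current RNG
#' state (seed the RNG for reproducible sequences).
#'
#' @param state an \code{ala_state}.
#' @return grid index.
#' @export
select_next_random <- function(state) {
  cand <- unsampled_indices(state)
  if (!length(cand)) stop("all grid points already sampled")
  cand[sample.int(length(cand), 1L)]
}

#' Select the next parameter point (uniform baseline)
#'
#' The next point of the coarse uniform sub-grid in sweep order (r varies
#' fastest), skipping points that already have data. Signals exhaustion
#' once the sub-grid is spent.
#'
#' @param state an \code{ala_state} created with strategy "uniform".
#' @return grid index.
#' @export
select_next_uniform <- function(state) {
  if (state$strategy != "uniform") stop("state was not built for the uniform strategy")
  cand <- setdiff(state$subgrid_idx, state$sampled)
  if (!length(cand)) stop("uniform sub-grid exhausted")
  cand[1]
}

#' Termination test of the sampling loop
#'
#' The loop stops when the residual map is everywhere strictly below the
#' threshold, or when every grid point has data.
#'
#' @param state an \code{ala_state}.
#' @return list with logical \code{stop} and character \code{reason}.
#' @export
check_termination <- function(state) {
  if (length(state$sampled) == nrow(state$grid$points))
    return(list(stop = TRUE, reason = "all grid points sampled"))
  if (!anyNA(state$residual_map) && max(state$residual_map) < state$threshold)
    return(list(stop = TRUE,
                reason = sprintf("residual loss below threshold (max %.4g < %g)",
                                 max(state$residual_map), state$threshold)))
  list(stop = FALSE, reason = "residual above threshold and grid not exhausted")
}

# --- oracle data extraction ---------------------------------------------

#' Convert a FEM solution into training samples
#'
#' One sample per vertex node: position, parameters, nodal velocity and
#' boundary tag; plus the reference pressure interpolated at the anchor
#' location. A retained fraction \code{c_frac} < 1 keeps a uniform random
#' subsample of the nodes (the anchor is unaffected).
#'
#' @param sol a \code{fem_solution}.
#' @param c_frac retained fraction of nodes, in (0, 1].
#' @param anchor (x, y) of the per-theta reference pressure location.
#' @return list with data.frames \code{samples} and \code{anchor}.
#' @export
fem_training_data <- function(sol, c_frac = 1, anchor = c(95, 5)) {
  stopifnot(inherits(sol, "fem_solution"), c_frac > 0, c_frac <= 1)
  mesh <- sol$mesh
  v1 <- p2_vertex_values(mesh)
  samples <- data.frame(
    x = mesh$p1$nodes[, 1], y = mesh$p1$nodes[, 2],
    f = sol$theta$f, r = sol$theta$r,
    ux = sol$ux[v1], uy = sol$uy[v1],
    tag = mesh$p1$tag, stringsAsFactors = FALSE
  )
  if (c_frac < 1) {
    keep <- sort(sample.int(nrow(samples), ceiling(c_frac * nrow(samples))))
    samples <- samples[keep, , drop = FALSE]
    rownames(samples) <- NULL
  }
  anchor_p <- interp_vertex_field(mesh, sol$p, rbind(anchor))
  list(samples = samples,
       anchor = data.frame(x = anchor[1], y = anchor[2],
                           f = sol$theta$f, r = sol$theta$r, p = anchor_p))
}

#' Assemble a training set
#'
#' Pools per-theta sample tables and anchors into the structure consumed
#' by \code{\link{train_pinn}}. Validates that every sampled theta carries
#' exactly one reference pressure and a non-empty Dirichlet boundary
#' subset.
#'
#' @param per_theta list of \code{\link{fem_training_data}} results.
#' @param c_frac the retained data fraction (book-keeping).
#' @return object of class \code{training_set}.
#' @export
make_training_set <- function(per_theta, c_frac = 1) {
  stopifnot(length(per_theta) > 0)
  samples <- do.call(rbind, lapply(per_theta, `[[`, "samples"))
  anchors <- do.call(rbind, lapply(per_theta, `[[`, "anchor"))
  rownames(samples) <- rownames(anchors) <- NULL
  key <- paste(signif(anchors$f, 10), signif(anchors$r, 10))
  if (anyDuplicated(key)) stop("duplicate reference pressure for a theta")
  for (k in seq_len(nrow(anchors))) {
    sel <- samples$f == anchors$f[k] & samples$r == anchors$r[k]
    if (!any(samples$tag[sel] %in% c("wall", "inflow")))
      stop("no Dirichlet boundary samples retained for theta ", key[k])
  }
  structure(
    list(samples = samples, anchors = anchors,
         meta = list(n = nrow(samples), b = nrow(anchors), c = c_frac)),
    class = "training_set"
  )
}

#' @exportS3Method base::print
print.training_set <- function(x, ...) {
  cat(sprintf("training set: %d samples over %d parameter points (c = %g)\n",
              x$meta$n, x$meta$b, x$meta$c))
  invisible(x)
}

#' Run the active-learning loop
#'
#' The full loop: train the surrogate on all data gathered so far, compute
#' the residual map over G, stop if it is everywhere below the threshold
#' (or G is exhausted), otherwise select a new parameter point by the
#' configured strategy, run the mesh generator and the Navier-Stokes
#' oracle there, append the new data (never discarding old data, so
#' nothing already learned is lost), and repeat. Initial data are the
#' corners and centre of the region.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param references optional list of reference \code{fem_solution}s
#'   indexed by grid row; if supplied, per-iteration L2 error reports (and
#'   hence the total error E) are recorded in the history.
#' @param fem_cache optional environment caching FEM solutions across runs
#'   (keyed by theta and mesh size).
#' @return list of class \code{ala_run}: final \code{pinn}, final
#'   \code{state}, final \code{training set}, and \code{history} — one
#'   record per iteration with the sampled set, residual map, selected
#'   point, loss components and (optionally) per-theta squared errors.
#' @export
run_ala <- function(config, references = NULL, fem_cache = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  grid <- build_grid(config$region, config$grid_spacing)
  props <- fluid_properties(config$rho, config$mu)
  weights <- do.call(loss_weights, as.list(config$weights))
  schedule <- training_schedule(config$adam_iters, config$adam_lr,
                                config$lbfgs_iters)
  netcfg <- network_config(config$hidden_layers, config$width)
  mesh_cache <- new.env(parent = emptyenv())

  state <- new_ala_state(grid, config$strategy, config$threshold, config$seed)
  pinn <- init_network(netcfg, seed = config$seed)

  init_idx <- match_grid_points(grid, corners_and_centre(config$region))
  if (anyNA(init_idx))
    stop("corners-and-centre points do not lie on the parameter grid")

  oracle <- function(idx) {
    theta <- as.list(grid$points[idx, ])
    mesh <- get_cached_mesh(theta$r, config$target_nodes, mesh_cache)
    sol <- fem_oracle_solve(mesh, theta, props, config, fem_cache)
    fem_training_data(sol, c_frac = config$c_frac)
  }

  per_theta <- list()
  for (idx in init_idx) per_theta[[as.character(idx)]] <- oracle(idx)
  state$sampled <- init_idx
  tset <- make_training_set(per_theta, config$c_frac)

  history <- list()
  repeat {
    pinn <- train_pinn(pinn, tset, weights, schedule, props)
    state$residual_map <- acquisition_map(pinn, grid, props,
                                          config$target_nodes, mesh_cache)
    last <- pinn$history[[length(pinn$history)]]
    rec <- list(
      iteration = state$iteration,
      sampled = state$sampled,
      residual_map = state$residual_map,
      loss = c(total = tail(last$total, 1), lu = tail(last$lu, 1),
               lns = tail(last$lns, 1), lp = tail(last$lp, 1),
               lbc = tail(last$lbc, 1)),
      selected = NA_integer_
    )
    if (!is.null(references)) {
      reports <- do.call(rbind, lapply(seq_len(nrow(grid$points)), function(i)
        evaluation_report(references[[i]], pinn, props)))
      rec$reports <- reports
      rec$E <- total_error_E(reports, grid)
    }
    term <- check_termination(state)
    done <- term$stop || state$iteration >= config$max_iters
    if (!done) {
      idx <- switch(config$strategy,
                    active = select_next_active(state),
                    random = select_next_random(state),
                    uniform = tryCatch(select_next_uniform(state),
                                       error = function(e) NA_integer_))
      if (is.na(idx)) {
        term <- list(stop = TRUE, reason = "uniform sub-grid exhausted")
        done <- TRUE
      } else {
        rec$selected <- idx
      }
    }
    history[[length(history) + 1L]] <- rec
    if (done) {
      attr(history, "termination") <-
        if (term$stop) term$reason else "iteration budget reached"
      break
    }
    new_data <- tryCatch(oracle(rec$selected), error = function(e) e)
    if (inherits(new_data, "error")) {
      attr(history, "termination") <-
        paste0("oracle failure at grid index ", rec$selected, ": ",
               conditionMessage(new_data))
      break
    }
    per_theta[[as.character(rec$selected)]] <- new_data
    state$sampled <- c(state$sampled, rec$selected)
    tset <- make_training_set(per_theta, config$c_frac)
    state$iteration <- state$iteration + 1L
  }

  structure(list(pinn = pinn, state = state, training_set = tset,
                 history = history, config = config),
            class = "ala_run")
}

fem_oracle_solve <- function(mesh, theta, props, config, fem_cache = NULL) {
  if (is.null(fem_cache))
    return(solve_navier_stokes(mesh, theta, props,
                               tol = config$newton_tol,
                               max_newton = config$max_newton))
  key <- sprintf("%.12g_%.12g_%d", theta$f, theta$r,
                 as.integer(config$target_nodes))
  if (is.null(fem_cache[[key]]))
    fem_cache[[key]] <- solve_navier_stokes(mesh, theta, props,
                                            tol = config$newton_tol,
                                            max_newton = config$max_newton)
  fem_cache[[key]]
}

#' @exportS3Method base::print
print.ala_run <- function(x, ...) {
  cat(sprintf("ALA run (%s): %d iterations, %d grid points sampled\n",
              x$config$strategy, length(x$history) - 1L,
              length(x$state$sampled)))
  cat("  termination:", attr(x$history, "termination"), "\n")
  if (!is.null(x$history[[length(x$history)]]$E))
    cat(sprintf("  final total error E = %.4g\n",
                x$history[[length(x$history)]]$E))
  invisible(x)
}
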