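#' Network architecture configuration
#'
#' A fully-connected tanh network with four inputs (x, y, f, r) and two
#' outputs: a stream function psi (whose rotated gradient is the velocity)
#' and the pressure p. Defaults: four hidden layers of eighty neurons.
#'
#' Inputs are affinely rescaled to order one inside the network (shifts
#' 50, 5, 0, 0 and scales 50, 5, 2, 2 for x, y, f, r, from the tube and
#' design-region extents); this is a conditioning device only — all
#' derivatives and losses are with respect to the raw mm coordinates, and
#' predictions are invariant to it up to training.
#'
#' Symmetrically, the two raw outputs are multiplied by fixed scales
#' (10 for the stream function, 0.1 for the pressure in Pa), chosen from
#' the largest inflow flux (20 f / 3, about 13 mm^2/s at f = 2) and the
#' Poiseuille pressure-drop scale, so the network itself works at order
#' one.
#'
#' @param hidden_layers number of hidden layers (>= 1).
#' @param width neurons per hidden layer (>= 1).
#' @param in_shift,in_scale length-4 affine input normalisation.
#' @param out_scale length-2 output scaling (stream function, pressure).
#' @return list of class \code{network_config}.
#' @export
network_config <- function(hidden_layers = 4, width = 80,
                           in_shift = c(50, 5, 0, 0),
                           in_scale = c(50, 5, 2, 2),
                           out_scale = c(10, 0.1)) {
  stopifnot(hidden_layers >= 1, width >= 1,
            length(in_shift) == 4, length(in_scale) == 4, all(in_scale > 0),
            length(out_scale) == 2, all(out_scale > 0))
  structure(
    list(sizes = as.integer(c(4, rep(width, hidden_layers), 2)),
         in_shift = as.numeric(in_shift), in_scale = as.numeric(in_scale),
         out_scale = as.numeric(out_scale)),
    class = "network_config"
  )
}

#' Loss component weights
#'
#' Relative weights of the four loss components: velocity data, momentum
#' residual, reference pressure, and boundary condition. Defaults
#' (1, 1e6, 1e2, 1e6).
#'
#' @param alpha_u,alpha_ns,alpha_p,alpha_bc non-negative scalars.
#' @return named numeric vector of class \code{loss_weights}.
#' @export
loss_weights <- function(alpha_u = 1, alpha_ns = 1e6, alpha_p = 1e2,
                         alpha_bc = 1e6) {
  w <- c(alpha_u = alpha_u, alpha_ns = alpha_ns,
         alpha_p = alpha_p, alpha_bc = alpha_bc)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(w, class = "loss_weights")
}

n_params <- function(sizes) {
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

#' Initialise a network
#'
#' Weights are drawn from a zero-mean truncated normal (truncated at two
#' standard deviations of the generating normal and rescaled so that the
#' post-truncation variance equals 2 / (N_in + N_out) for each layer);
#' biases start at zero. Reproducible given the seed.
#'
#' @param config a \code{\link{network_config}}.
#' @param seed integer RNG seed.
#' @return object of class \code{pinn} holding the flat parameter vector,
#'   the architecture, and an (initially empty) training history.
#' @export
init_network <- function(config = network_config(), seed = 1) {
  stopifnot(inherits(config, "network_config"))
  sizes <- config$sizes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # truncation at 2 sd removes tail variance; 0.87962566 is the std. dev. of
  # a standard normal truncated to [-2, 2], used to rescale back to target
  trunc_correction <- 0.87962566103423978
  par <- numeric(0)
  for (l in seq_len(length(sizes) - 1)) {
    nin <- sizes[l]; nout <- sizes[l + 1]
    sd_target <- sqrt(2 / (nin + nout))
    sd_gen <- sd_target / trunc_correction
    u <- stats::runif(nin * nout, stats::pnorm(-2), stats::pnorm(2))
    par <- c(par, stats::qnorm(u) * sd_gen, numeric(nout))
  }
  structure(
    list(par = par, config = config, seed = as.integer(seed),
         history = list()),
    class = "pinn"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @exportS3Method base::print
print.pinn <- function(x, ...) {
  s <- x$config$sizes
  cat(sprintf("stream-function/pressure network: %s (%d parameters)\n",
              paste(s, collapse = "-"), length(x$par)))
  if (length(x$history))
    cat(sprintf("  trained %d stage(s); final total loss %.4g\n",
                length(x$history), tail(x$history[[length(x$history)]]$total, 1)))
  invisible(x)
}

as_X <- function(x, y, f, r) {
  n <- max(length(x), length(y), length(f), length(r))
  cbind(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
        rep_len(as.numeric(f), n), rep_len(as.numeric(r), n))
}

#' Evaluate the surrogate fields
#'
#' Forward evaluation of the network and its derived physical fields at
#' arbitrary points: stream function, pressure, the divergence-free
#' velocity (u, v) = (dpsi/dy, -dpsi/dx), and the two components of the
#' steady momentum residual rho (u.grad) u + grad p - mu lap(u), all from
#' exact analytic derivatives of the network.
#'
#' @param state a \code{pinn}.
#' @param x,y coordinates in mm (recycled to a common length).
#' @param f,r parameter-space coordinates (recycled).
#' @param props \code{\link{fluid_properties}} used for the residual.
#' @return data.frame with columns psi, p, u, v, r1, r2.
#' @export
pinn_fields <- function(state, x, y, f, r, props = fluid_properties()) {
  stopifnot(inherits(state, "pinn"))
  X <- as_X(x, y, f, r)
  out <- pinn_fields_cpp(state$par, state$config$sizes, X,
                         state$config$in_shift, state$config$in_scale,
                         state$config$out_scale, props$rho, props$mu)
  colnames(out) <- c("psi", "p", "u", "v", "r1", "r2")
  as.data.frame(out)
}

#' Velocity from the stream function
#'
#' The velocity induced by the network's scalar potential,
#' (u, v) = (dpsi/dy, -dpsi/dx), via exact derivatives (not finite
#' differences). Divergence-free by construction.
#'
#' @inheritParams pinn_fields
#' @return two-column matrix (u, v) in mm/s.
#' @export
velocity_from_potential <- function(state, x, y, f, r) {
  fl <- pinn_fields(state, x, y, f, r)
  cbind(u = fl$u, v = fl$v)
}

#' Momentum residual of the surrogate
#'
#' @inheritParams pinn_fields
#' @return two-column matrix of the x and y momentum residual components.
#' @export
ns_residual <- function(state, x, y, f, r, props = fluid_properties()) {
  fl <- pinn_fields(state, x, y, f, r, props)
  cbind(r1 = fl$r1, r2 = fl$r2)
}

#' All derivative channels of the network outputs
#'
#' Returns the raw derivative channels (value; x, y; xx, xy, yy; xxx, xxy,
#' xyy, yyy) of both network outputs, mainly for verification against
#' finite differences.
#'
#' @inheritParams pinn_fields
#' @return list with matrices \code{psi} and \code{p}, one column per
#'   channel.
#' @export
pinn_channels <- function(state, x, y, f, r) {
  X <- as_X(x, y, f, r)
  ch <- pinn_channels_cpp(state$par, state$config$sizes, X,
                          state$config$in_shift, state$config$in_scale,
                          state$config$out_scale)
  cn <- c("v", "x", "y", "xx", "xy", "yy", "xxx", "xxy", "xyy", "yyy")
  colnames(ch$psi) <- cn; colnames(ch$p) <- cn
  ch
}

check_samples <- function(samples, cols) {
  stopifnot(is.data.frame(samples), all(cols %in% names(samples)))
  if (nrow(samples) == 0) stop("empty sample set")
  samples
}

#' Velocity data loss
#'
#' Unnormalised sum over samples of the squared Euclidean error between the
#' surrogate velocity and the data velocity.
#'
#' @param state a \code{pinn}.
#' @param samples data.frame with columns x, y, f, r, ux, uy.
#' @return scalar.
#' @export
loss_velocity <- function(state, samples) {
  samples <- check_samples(samples, c("x", "y", "f", "r", "ux", "uy"))
  uv <- velocity_from_potential(state, samples$x, samples$y, samples$f, samples$r)
  sum((uv[, 1] - samples$ux)^2 + (uv[, 2] - samples$uy)^2)
}

#' Momentum residual loss
#'
#' Unnormalised sum over collocation points of the squared Euclidean norm
#' of the momentum residual. No reference data enter this term.
#'
#' @param state a \code{pinn}.
#' @param colloc data.frame with columns x, y, f, r.
#' @param props \code{\link{fluid_properties}}.
#' @return scalar.
#' @export
loss_ns <- function(state, colloc, props = fluid_properties()) {
  colloc <- check_samples(colloc, c("x", "y", "f", "r"))
  rs <- ns_residual(state, colloc$x, colloc$y, colloc$f, colloc$r, props)
  sum(rs[, 1]^2 + rs[, 2]^2)
}

#' Reference-pressure anchor loss
#'
#' One reference pressure per sampled parameter point pins the additive
#' pressure constant (the pressure is otherwise defined only up to a
#' constant per theta).
#'
#' @param state a \code{pinn}.
#' @param refs data.frame with columns x, y, f, r, p (one row per sampled
#'   parameter point).
#' @return scalar.
#' @export
loss_pressure_anchor <- function(state, refs) {
  refs <- check_samples(refs, c("x", "y", "f", "r", "p"))
  if (anyNA(refs$p)) stop("missing reference pressure")
  fl <- pinn_fields(state, refs$x, refs$y, refs$f, refs$r)
  sum((refs$p - fl$p)^2)
}

#' Boundary-condition loss
#'
#' Sum of squared velocity errors against the imposed Dirichlet data: zero
#' on the walls and the parabolic profile (I_f(y), 0) on the inflow. The
#' outflow carries no Dirichlet velocity condition, so outflow-tagged
#' samples are rejected.
#'
#' @param state a \code{pinn}.
#' @param samples data.frame with columns x, y, f, r, tag (wall or inflow).
#' @return scalar.
#' @export
loss_boundary <- function(state, samples) {
  samples <- check_samples(samples, c("x", "y", "f", "r", "tag"))
  if (any(!samples$tag %in% c("wall", "inflow")))
    stop("boundary loss accepts only wall or inflow tags; outflow carries ",
         "no Dirichlet velocity condition")
  g <- boundary_targets(samples)
  uv <- velocity_from_potential(state, samples$x, samples$y, samples$f, samples$r)
  sum((uv[, 1] - g[, 1])^2 + (uv[, 2] - g[, 2])^2)
}

boundary_targets <- function(samples) {
  gx <- numeric(nrow(samples))
  infl <- samples$tag == "inflow"
  if (any(infl)) gx[infl] <- inflow_profile(1, samples$y[infl]) * samples$f[infl]
  cbind(gx, 0)
}

#' Total training loss
#'
#' Weighted sum of the four components, with the raw components reported
#' separately.
#'
#' @param state a \code{pinn}.
#' @param tset a \code{\link{training_set}}.
#' @param weights \code{\link{loss_weights}}.
#' @param props \code{\link{fluid_properties}}.
#' @return list with \code{total} and \code{components} (lu, lns, lp, lbc).
#' @export
total_loss <- function(state, tset, weights = loss_weights(),
                       props = fluid_properties()) {
  d <- training_design(tset)
  res <- pinn_loss_cpp(state$par, state$config$sizes, d$X,
                       state$config$in_shift, state$config$in_scale,
                       state$config$out_scale,
                       d$U, d$Gbc, d$pref, d$wu, d$wns, d$wbc, d$wp,
                       as.numeric(weights), props$rho, props$mu, FALSE)
  list(total = res$total,
       components = c(lu = res$lu, lns = res$lns, lp = res$lp, lbc = res$lbc))
}

# flatten a training set into the kernel's design matrices; anchor rows are
# appended after the sample rows and participate only in the pressure term
training_design <- function(tset) {
  stopifnot(inherits(tset, "training_set"))
  s <- tset$samples; a <- tset$anchors
  n <- nrow(s); m <- nrow(a)
  X <- rbind(as_X(s$x, s$y, s$f, s$r), as_X(a$x, a$y, a$f, a$r))
  U <- rbind(cbind(s$ux, s$uy), matrix(0, m, 2))
  is_bc <- s$tag %in% c("wall", "inflow")
  Gbc <- rbind(boundary_targets(s), matrix(0, m, 2))
  pref <- c(numeric(n), a$p)
  list(X = X, U = U, Gbc = Gbc, pref = pref,
       wu = c(rep(1, n), numeric(m)),
       wns = c(rep(1, n), numeric(m)),
       wbc = c(as.numeric(is_bc), numeric(m)),
       wp = c(numeric(n), rep(1, m)))
}

#' Optimiser schedule
#'
#' Two training stages: first-order Adam (default 20000 iterations at
#' learning rate 1e-4), then L-BFGS-B (default cap 50000 iterations).
#'
#' @param adam_iters,adam_lr,lbfgs_iters stage controls.
#' @return list of class \code{training_schedule}.
#' @export
training_schedule <- function(adam_iters = 20000, adam_lr = 1e-4,
                              lbfgs_iters = 50000) {
  stopifnot(adam_iters >= 0, adam_lr > 0, lbfgs_iters >= 0)
  structure(list(adam_iters = as.integer(adam_iters), adam_lr = adam_lr,
                 lbfgs_iters = as.integer(lbfgs_iters)),
            class = "training_schedule")
}

#' Train the network on a training set
#'
#' Full-batch two-stage optimisation of the weighted loss: Adam followed by
#' L-BFGS-B (\code{stats::optim}). Deterministic given the starting state
#' (no randomness enters training itself). Loss components are recorded per
#' Adam iteration and per quasi-Newton evaluation. Aborts with a component
#' diagnostic if the loss becomes non-finite.
#'
#' @param state a \code{pinn} (possibly already trained: warm start).
#' @param tset a \code{\link{training_set}}.
#' @param weights \code{\link{loss_weights}}.
#' @param schedule \code{\link{training_schedule}}.
#' @param props \code{\link{fluid_properties}}.
#' @return the trained \code{pinn}, with a new entry appended to
#'   \code{$history} holding per-iteration component traces.
#' @export
train_pinn <- function(state, tset, weights = loss_weights(),
                       schedule = training_schedule(),
                       props = fluid_properties()) {
  stopifnot(inherits(state, "pinn"), inherits(schedule, "training_schedule"))
  d <- training_design(tset)
  sizes <- state$config$sizes
  shift <- state$config$in_shift; scale <- state$config$in_scale
  oscale <- state$config$out_scale
  alpha <- as.numeric(weights)
  eval_loss <- function(par, want_grad) {
    pinn_loss_cpp(par, sizes, d$X, shift, scale, oscale, d$U, d$Gbc, d$pref,
                  d$wu, d$wns, d$wbc, d$wp, alpha, props$rho, props$mu,
                  want_grad)
  }
  check_finite <- function(res, where) {
    if (!is.finite(res$total)) {
      comps <- c(lu = res$lu, lns = res$lns, lp = res$lp, lbc = res$lbc)
      bad <- names(comps)[!is.finite(comps)]
      stop("non-finite loss during ", where, "; offending component(s): ",
           if (length(bad)) paste(bad, collapse = ", ") else "total only")
    }
  }

  par <- state$par
  trace <- list(total = numeric(0), lu = numeric(0), lns = numeric(0),
                lp = numeric(0), lbc = numeric(0), stage = character(0))
  push <- function(res, stage) {
    trace$total <<- c(trace$total, res$total)
    trace$lu <<- c(trace$lu, res$lu); trace$lns <<- c(trace$lns, res$lns)
    trace$lp <<- c(trace$lp, res$lp); trace$lbc <<- c(trace$lbc, res$lbc)
    trace$stage <<- c(trace$stage, stage)
  }

  # stage 1: Adam
  if (schedule$adam_iters > 0) {
    m <- numeric(length(par)); v <- numeric(length(par))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (it in seq_len(schedule$adam_iters)) {
      res <- eval_loss(par, TRUE)
      check_finite(res, sprintf("Adam iteration %d", it))
      push(res, "adam")
      g <- res$grad
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^it); vhat <- v / (1 - b2^it)
      par <- par - schedule$adam_lr * mhat / (sqrt(vhat) + eps)
    }
  }

  # stage 2: L-BFGS-B
  if (schedule$lbfgs_iters > 0) {
    fn <- function(p) {
      res <- eval_loss(p, FALSE)
      check_finite(res, "quasi-Newton stage")
      push(res, "lbfgs")
      res$total
    }
    gr <- function(p) eval_loss(p, TRUE)$grad
    start_total <- eval_loss(par, FALSE)$total
    # memory 20: the alpha-weighted objective mixes curvature scales over
    # six orders of magnitude, and short-memory updates stall on it
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = schedule$lbfgs_iters,
                                       factr = 10, lmm = 20))
    if (opt$value <= start_total) par <- opt$par
  }

  state$par <- par
  state$history <- c(state$history, list(trace))
  state
}

#' Save / load a network checkpoint
#'
#' Plain-JSON checkpoint of the architecture, input normalisation, flat
#' parameter vector and per-stage final losses.
#'
#' @param state a \code{pinn}.
#' @param path file path.
#' @return \code{load_pinn} returns the restored \code{pinn}.
#' @export
save_pinn <- function(state, path) {
  stopifnot(inherits(state, "pinn"))
  obj <- list(
    sizes = state$config$sizes,
    in_shift = state$config$in_shift,
    in_scale = state$config$in_scale,
    out_scale = state$config$out_scale,
    seed = state$seed,
    par = state$par,
    stage_final_loss = vapply(state$history,
                              function(h) tail(h$total, 1), numeric(1))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pinn
#' @export
load_pinn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(hidden_layers = length(obj$sizes) - 2,
                        width = if (length(obj$sizes) > 2) obj$sizes[2] else 1,
                        in_shift = obj$in_shift, in_scale = obj$in_scale,
                        out_scale = obj$out_scale)
  cfg$sizes <- as.integer(obj$sizes)
  structure(list(par = as.numeric(obj$par), config = cfg,
                 seed = obj$seed, history = list()),
            class = "pinn")
}
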