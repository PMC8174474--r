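test_that("initialisation is reproducible with the stated layer variance", {
  cfg <- network_config(4, 80)
  a <- init_network(cfg, seed = 11)
  b <- init_network(cfg, seed = 11)
  expect_identical(a$par, b$par)
  expect_false(identical(a$par, init_network(cfg, seed = 12)$par))

  # first layer: 4 inputs, 80 outputs -> target variance 2 / 84
  w1 <- a$par[seq_len(4 * 80)]
  expect_lt(abs(var(w1) - 2 / 84) / (2 / 84), 0.2)
  # truncation: no draw beyond two generating standard deviations
  sd_gen <- sqrt(2 / 84) / 0.87962566103423978
  expect_lte(max(abs(w1)), 2 * sd_gen)
  # biases start at zero
  expect_equal(a$par[4 * 80 + seq_len(80)], numeric(80))
})

test_that("forward evaluation is batched, finite and order-invariant", {
  net <- tiny_net()
  pts <- random_points(50)
  fl <- pinn_fields(net, pts$x, pts$y, pts$f, pts$r)
  expect_equal(nrow(fl), 50)
  expect_true(all(is.finite(as.matrix(fl))))

  perm <- sample(50)
  fl2 <- pinn_fields(net, pts$x[perm], pts$y[perm], pts$f[perm], pts$r[perm])
  expect_equal(as.matrix(fl2), as.matrix(fl)[perm, ], tolerance = 1e-14)
})

test_that("velocity is the rotated gradient of the stream function", {
  net <- tiny_net()
  pts <- random_points(40, seed = 3)
  uv <- velocity_from_potential(net, pts$x, pts$y, pts$f, pts$r)
  ch <- pinn_channels(net, pts$x, pts$y, pts$f, pts$r)
  expect_equal(uv[, 1], ch$psi[, "y"])
  expect_equal(uv[, 2], -ch$psi[, "x"])

  # against central differences of the scalar potential itself
  h <- 1e-3
  psi_yp <- pinn_fields(net, pts$x, pts$y + h, pts$f, pts$r)$psi
  psi_ym <- pinn_fields(net, pts$x, pts$y - h, pts$f, pts$r)$psi
  psi_xp <- pinn_fields(net, pts$x + h, pts$y, pts$f, pts$r)$psi
  psi_xm <- pinn_fields(net, pts$x - h, pts$y, pts$f, pts$r)$psi
  expect_equal(uv[, 1], (psi_yp - psi_ym) / (2 * h), tolerance = 1e-6)
  expect_equal(uv[, 2], -(psi_xp - psi_xm) / (2 * h), tolerance = 1e-6)
})

test_that("the induced velocity field is divergence-free", {
  net <- tiny_net()
  pts <- random_points(200, seed = 5)
  h <- 5e-3
  dudx <- (velocity_from_potential(net, pts$x + h, pts$y, pts$f, pts$r)[, 1] -
           velocity_from_potential(net, pts$x - h, pts$y, pts$f, pts$r)[, 1]) / (2 * h)
  dvdy <- (velocity_from_potential(net, pts$x, pts$y + h, pts$f, pts$r)[, 2] -
           velocity_from_potential(net, pts$x, pts$y - h, pts$f, pts$r)[, 2]) / (2 * h)
  expect_lt(max(abs(dudx + dvdy)), 1e-8)
})

test_that("the momentum residual matches a finite-difference oracle", {
  net <- tiny_net()
  pts <- random_points(25, seed = 9)
  props <- fluid_properties()
  got <- ns_residual(net, pts$x, pts$y, pts$f, pts$r, props)

  # oracle uses only velocity/pressure evaluations and central differences
  h <- 1e-2
  ev <- function(dx, dy) pinn_fields(net, pts$x + dx, pts$y + dy, pts$f, pts$r)
  c0 <- ev(0, 0); cxp <- ev(h, 0); cxm <- ev(-h, 0)
  cyp <- ev(0, h); cym <- ev(0, -h)
  d_x <- function(fld) (cxp[[fld]] - cxm[[fld]]) / (2 * h)
  d_y <- function(fld) (cyp[[fld]] - cym[[fld]]) / (2 * h)
  lap <- function(fld) (cxp[[fld]] + cxm[[fld]] + cyp[[fld]] + cym[[fld]] -
                        4 * c0[[fld]]) / h^2
  r1_fd <- props$rho * (c0$u * d_x("u") + c0$v * d_y("u")) + d_x("p") -
    props$mu * lap("u")
  r2_fd <- props$rho * (c0$u * d_x("v") + c0$v * d_y("v")) + d_y("p") -
    props$mu * lap("v")
  scale <- max(abs(got))
  expect_lt(max(abs(got[, 1] - r1_fd)) / scale, 1e-5)
  expect_lt(max(abs(got[, 2] - r2_fd)) / scale, 1e-5)
})

test_that("residual algebra annihilates the manufactured Poiseuille fields", {
  # cross-check the R-side channel combination against the kernel first
  net <- tiny_net()
  pts <- random_points(30, seed = 13)
  ch <- pinn_channels(net, pts$x, pts$y, pts$f, pts$r)
  r_ch <- residual_from_channels(ch)
  r_k <- ns_residual(net, pts$x, pts$y, pts$f, pts$r)
  expect_equal(unname(r_ch), unname(r_k), tolerance = 1e-12)

  # exact closed-form channels of fully developed channel flow
  set.seed(2)
  x <- runif(100, 0, 100); y <- runif(100, 0, 10)
  pois <- poiseuille_channels(x, y, f = 1.5)
  r <- residual_from_channels(pois)
  expect_lt(max(abs(r)), 1e-12)
  expect_lt(sum(r[, 1]^2 + r[, 2]^2), 1e-12)
})

test_that("loss components follow their definitions on hand-made cases", {
  zn <- zero_net()
  # a zero network predicts zero velocity: squared-error sums are explicit
  one <- data.frame(x = 40, y = 6, f = 1, r = 0.5, ux = 3, uy = 4)
  expect_equal(loss_velocity(zn, one), 25)
  expect_equal(loss_velocity(zn, rbind(one, one)), 50)
  expect_error(loss_velocity(zn, one[0, ]), "empty")

  expect_equal(loss_ns(zn, data.frame(x = 40, y = 6, f = 1, r = 0.5)), 0)

  bc <- data.frame(x = c(30, 0), y = c(wall_halfwidth(30, 0.5) + 5, 5),
                   f = 1.5, r = 0.5, tag = c("wall", "inflow"))
  # zero net: wall contributes 0, the inflow point contributes I_f(5)^2
  expect_equal(loss_boundary(zn, bc), inflow_profile(1.5, 5)^2)
  bad <- bc; bad$tag[1] <- "outflow"
  expect_error(loss_boundary(zn, bad), "outflow")

  refs <- data.frame(x = 95, y = 5, f = c(1, -1), r = c(0.5, 0), p = 0)
  net <- tiny_net()
  refs$p <- pinn_fields(net, refs$x, refs$y, refs$f, refs$r)$p
  expect_equal(loss_pressure_anchor(net, refs), 0)
  refs$p <- refs$p + 0.1  # constant shift of all M anchors
  expect_equal(loss_pressure_anchor(net, refs), nrow(refs) * 0.01)
})

test_that("total loss equals the weighted sum of independent components", {
  net <- tiny_net()
  set.seed(4)
  n <- 40
  samples <- data.frame(
    x = runif(n, 0, 100), y = runif(n, 0, 10),
    f = runif(n, -2, 2), r = runif(n, -1, 1),
    ux = rnorm(n), uy = rnorm(n),
    tag = sample(c("interior", "wall", "inflow", "outflow"), n, TRUE))
  anchors <- data.frame(x = 95, y = 5, f = c(0.5, -1.5), r = c(0, 1),
                        p = c(0.03, -0.02))
  tset <- structure(list(samples = samples, anchors = anchors,
                         meta = list(n = n, b = 2, c = 1)),
                    class = "training_set")
  w <- loss_weights(2, 1e5, 10, 1e4)
  tl <- total_loss(net, tset, w)

  lu <- loss_velocity(net, samples)
  lns <- loss_ns(net, samples)
  lbc <- loss_boundary(net, samples[samples$tag %in% c("wall", "inflow"), ])
  lp <- loss_pressure_anchor(net, anchors)
  expect_equal(unname(tl$components),
               c(lu, lns, lp, lbc), tolerance = 1e-12)
  expect_equal(tl$total, 2 * lu + 1e5 * lns + 10 * lp + 1e4 * lbc,
               tolerance = 1e-12)
})

test_that("training reduces the data misfit and is deterministic", {
  set.seed(1)
  mesh <- fixture("mesh_straight_300",
                  function() generate_mesh(tube_geometry(0), 300))
  sol <- ns_straight_300 <- fixture("ns_straight300_f15", function()
    solve_navier_stokes(mesh, list(f = 1.5, r = 0)))
  tset <- make_training_set(list(fem_training_data(sol, c_frac = 0.25)), 0.25)
  net <- init_network(network_config(2, 32), 1)
  lu0 <- loss_velocity(net, tset$samples)
  trained <- train_pinn(net, tset,
                        schedule = training_schedule(2000, 1e-4, 500))
  lu1 <- loss_velocity(trained, tset$samples)
  expect_lt(lu1 / lu0, 0.2)

  # the quasi-Newton stage never ends above its starting loss
  h <- trained$history[[1]]
  lb <- h$total[h$stage == "lbfgs"]
  expect_lte(tail(h$total, 1), lb[1])

  # identical Adam trajectories for identical starts
  a <- train_pinn(net, tset, schedule = training_schedule(50, 1e-4, 0))
  b <- train_pinn(net, tset, schedule = training_schedule(50, 1e-4, 0))
  expect_identical(a$par, b$par)
  expect_identical(a$history[[1]]$total, b$history[[1]]$total)

  # pure first-order schedule trains without a quasi-Newton stage
  expect_equal(sum(a$history[[1]]$stage == "lbfgs"), 0)

  # a diverging step size is reported with the offending component
  expect_error(train_pinn(net, tset,
                          schedule = training_schedule(5, 1e200, 0)),
               "non-finite")
})

test_that("checkpoints round-trip parameters and predictions", {
  net <- tiny_net()
  path <- tempfile(fileext = ".json")
  save_pinn(net, path)
  back <- load_pinn(path)
  expect_equal(back$par, net$par)
  expect_equal(back$config$sizes, net$config$sizes)
  pts <- random_points(10)
  expect_equal(pinn_fields(back, pts$x, pts$y, pts$f, pts$r),
               pinn_fields(net, pts$x, pts$y, pts$f, pts$r))
})
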