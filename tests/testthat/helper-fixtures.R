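# Shared fixtures, built once per test session on first use.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

straight_mesh <- function(target = 1000) {
  fixture(paste0("mesh_straight_", target),
          function() generate_mesh(tube_geometry(0), target))
}

ns_straight <- function(f, target = 1000) {
  fixture(sprintf("ns_straight_f%g_n%d", f, target), function()
    solve_navier_stokes(straight_mesh(target), list(f = f, r = 0)))
}

# a small randomly initialised network shared by derivative tests
tiny_net <- function(seed = 42) {
  fixture(paste0("tiny_net_", seed),
          function() init_network(network_config(2, 8), seed = seed))
}

# a network whose parameters are all zero: psi and p vanish identically
zero_net <- function(width = 8) {
  fixture(paste0("zero_net_", width), function() {
    net <- init_network(network_config(2, width), seed = 1)
    net$par[] <- 0
    net
  })
}

# random evaluation points inside the straight tube and the design region
random_points <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 100), y = runif(n, 0.5, 9.5),
             f = runif(n, -2, 2), r = runif(n, -1.5, 1.5))
}

# analytic derivative channels of the manufactured Poiseuille fields on the
# straight tube: psi = f (5 y^2 - y^3 / 3) / 25, p = (2 mu f / 25) (100 - x)
poiseuille_channels <- function(x, y, f, mu = 0.004) {
  n <- length(x)
  psi <- matrix(0, n, 10,
                dimnames = list(NULL, c("v", "x", "y", "xx", "xy", "yy",
                                        "xxx", "xxy", "xyy", "yyy")))
  psi[, "v"] <- f * (5 * y^2 - y^3 / 3) / 25
  psi[, "y"] <- f * y * (10 - y) / 25
  psi[, "yy"] <- f * (10 - 2 * y) / 25
  psi[, "yyy"] <- rep(-2 * f / 25, n)
  p <- matrix(0, n, 10, dimnames = dimnames(psi))
  p[, "v"] <- (2 * mu * f / 25) * (100 - x)
  p[, "x"] <- rep(-2 * mu * f / 25, n)
  list(psi = psi, p = p)
}

# momentum residual assembled from derivative channels; mirrors the kernel's
# head algebra and serves as its independent R-side counterpart
residual_from_channels <- function(ch, rho = 0.00106, mu = 0.004) {
  u <- ch$psi[, "y"]; v <- -ch$psi[, "x"]
  ux <- ch$psi[, "xy"]; uy <- ch$psi[, "yy"]
  vx <- -ch$psi[, "xx"]; vy <- -ch$psi[, "xy"]
  lap_u <- ch$psi[, "xxy"] + ch$psi[, "yyy"]
  lap_v <- -(ch$psi[, "xxx"] + ch$psi[, "xyy"])
  cbind(r1 = rho * (u * ux + v * uy) + ch$p[, "x"] - mu * lap_u,
        r2 = rho * (u * vx + v * vy) + ch$p[, "y"] - mu * lap_v)
}
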