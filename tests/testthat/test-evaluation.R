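test_that("piecewise-linear L2 quadrature is exact", {
  mesh <- fixture("mesh_straight_300",
                  function() generate_mesh(tube_geometry(0), 300))
  # constant difference c over a domain of area A integrates to c^2 A
  area <- sum(vastra:::signed_area2(mesh$p1$nodes, mesh$p1$tri)) / 2
  expect_equal(area, 1000, tolerance = 1e-10)  # straight tube: 100 x 10
  c0 <- 0.37
  expect_equal(sqrt(vastra:::l2sq_vertex_field(mesh, rep(c0, nrow(mesh$p1$nodes)))),
               c0 * sqrt(area), tolerance = 1e-12)

  # random nodal field against a dense Gauss-quadrature oracle
  set.seed(8)
  vals <- rnorm(nrow(mesh$p1$nodes))
  got <- vastra:::l2sq_vertex_field(mesh, vals)
  quad <- vastra:::tri_quadrature()  # degree-5 rule, exact for the square
  oracle <- 0
  for (e in seq_len(nrow(mesh$p1$tri))) {
    v <- mesh$p1$tri[e, ]
    a2 <- vastra:::signed_area2(mesh$p1$nodes, mesh$p1$tri[e, , drop = FALSE])
    for (q in seq_along(quad$w)) {
      d <- sum(quad$lambda[q, ] * vals[v])
      oracle <- oracle + quad$w[q] * a2 * d^2
    }
  }
  expect_equal(got, unname(oracle), tolerance = 1e-10)
})

test_that("field errors vanish for a perfect prediction and match identities", {
  sol <- fixture("ns_straight300_f15", function()
    solve_navier_stokes(fixture("mesh_straight_300", function()
      generate_mesh(tube_geometry(0), 300)), list(f = 1.5, r = 0)))
  zn <- zero_net()
  rep0 <- evaluation_report(sol, zn)
  # zero surrogate: velocity error is the norm of the FEM field itself
  v1 <- vastra:::p2_vertex_values(sol$mesh)
  expect_equal(rep0$l2_ux, sqrt(vastra:::l2sq_vertex_field(sol$mesh, sol$ux[v1])),
               tolerance = 1e-12)
  expect_equal(rep0$sq_total, rep0$l2_ux^2 + rep0$l2_uy^2 + rep0$l2_p^2)
  expect_equal(l2_field_error(sol, zn, "u_x"), rep0$l2_ux)

  # boundary errors of the zero surrogate: wall 0, inflow mean |I_f|
  expect_equal(boundary_nodal_error(sol, zn, "wall"), 0)
  infl_y <- sol$mesh$p1$nodes[sol$mesh$p1$tag == "inflow", 2]
  expect_equal(boundary_nodal_error(sol, zn, "inflow"),
               mean(abs(inflow_profile(1.5, infl_y))))
})

test_that("total error E sums squared L2 errors over the whole grid", {
  reports <- data.frame(f = c(-2, 0, 2), r = 0,
                        sq_total = c(1.5, 0.25, 2.25))
  expect_equal(total_error_E(reports), 4)

  g <- build_grid(list(f = c(-2, 2), r = c(0, 0)), 2)
  expect_equal(total_error_E(reports, g), 4)
  expect_error(total_error_E(reports[-2, ], g), "missing")

  # monotone: worsening one point cannot decrease E
  worse <- reports; worse$sq_total[2] <- 5
  expect_gt(total_error_E(worse), total_error_E(reports))
})

test_that("pressure sweep enumerates geometries and validates probes", {
  net <- tiny_net()
  sw <- pressure_sweep(net, f = 1.5, r_range = c(0, -2), step = 0.025)
  expect_equal(nrow(sw), 81)
  expect_equal(sw$r[1], 0)
  expect_equal(sw$r[81], -2)

  sw3 <- pressure_sweep(net, f = 1.5, r_range = c(0, -2), step = 1)
  expect_equal(nrow(sw3), 3)

  # the sweep queries the network only: values match direct field queries
  pa <- pinn_fields(net, 5, 5, 1.5, sw3$r)$p
  pb <- pinn_fields(net, 95, 5, 1.5, sw3$r)$p
  expect_equal(sw3$dp, pa - pb)

  expect_error(pressure_sweep(net, 1.5, c(0, -2), 0.025,
                              probes = list(a = c(50, 8.5), b = c(95, 5))),
               "outside")
  expect_error(pressure_sweep(net, 1.5, c(0, -2), 0.3), "divide")
})

test_that("target search returns the first rounded crossing from r = 0", {
  sweep <- data.frame(r = seq(0, -2, by = -0.25),
                      dp = seq(0.043, by = 0.004, length.out = 9))
  hit <- find_r_for_target(sweep, 0.051)
  expect_equal(as.numeric(hit), -0.5)
  expect_true(!is.null(attr(hit, "context")))

  # shuffled input: ordering is by r, not row position
  expect_equal(as.numeric(find_r_for_target(sweep[sample(9), ], 0.051)), -0.5)

  # target below the baseline: the straight tube already satisfies it
  expect_equal(as.numeric(find_r_for_target(sweep, 0.01)), 0)

  expect_error(find_r_for_target(sweep, 1), "never reached")
})
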