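test_that("parameter grid covers the region at the requested spacing", {
  g <- build_grid(design_region(), 1 / 3)
  expect_equal(nrow(g$points), 169)
  expect_length(g$f_values, 13)
  expect_length(g$r_values, 13)

  g2 <- build_grid(design_region(), 2)
  expect_equal(nrow(g2$points), 9)

  # row-major ordering, r fastest
  expect_equal(unlist(g2$points[1, ]), c(f = -2, r = -2))
  expect_equal(unlist(g2$points[2, ]), c(f = -2, r = 0))
  expect_equal(unlist(g2$points[4, ]), c(f = 0, r = -2))

  expect_error(build_grid(design_region(), 0), "positive")
  expect_error(build_grid(design_region(), 0.3), "divide")
})

test_that("corners-and-centre initialisation gives the five seed points", {
  cc <- corners_and_centre(design_region())
  expect_equal(nrow(cc), 5)
  expect_setequal(paste(cc$f, cc$r),
                  c("-2 -2", "-2 2", "2 -2", "2 2", "0 0"))

  # any non-degenerate rectangle gives five distinct points
  cc2 <- corners_and_centre(list(f = c(0, 1), r = c(-3, 5)))
  expect_equal(nrow(cc2), 5)

  # fully degenerate region collapses to a single deduplicated point
  cc3 <- corners_and_centre(list(f = c(0, 0), r = c(0, 0)))
  expect_equal(cc3, data.frame(f = 0, r = 0))
})

test_that("uniform sub-grid has 25 points swept with r fastest", {
  sub <- uniform_subgrid(design_region(), 1)
  expect_equal(nrow(sub), 25)
  expect_setequal(unique(sub$f), -2:2)
  # r exhausted before f advances
  expect_equal(sub$r[1:5], -2:2)
  expect_equal(sub$f[1:5], rep(-2, 5))
  expect_equal(sub$f[6], -1)

  expect_equal(nrow(uniform_subgrid(design_region(), 4)), 4)
  expect_error(uniform_subgrid(design_region(), 0.3), "divide")
})

test_that("wall half-width has exact ends, straight-tube recovery and symmetry", {
  expect_equal(wall_halfwidth(0, 1.7), 5)
  expect_equal(wall_halfwidth(100, -1.3), 5)
  expect_equal(wall_halfwidth(50, 0), 5)
  expect_equal(wall_halfwidth(50, -2), 3)
  x <- seq(0, 100, by = 2.5)
  expect_equal(wall_halfwidth(x, 0), rep(5, length(x)))
  expect_equal(wall_halfwidth(50 - x[x <= 50], 0.8),
               wall_halfwidth(50 + x[x <= 50], 0.8))
  # continuous in r
  expect_lt(max(abs(wall_halfwidth(x, 1) - wall_halfwidth(x, 1 + 1e-9))), 1e-8)
  expect_error(wall_halfwidth(101, 0), "within")
  expect_error(tube_geometry(-5), "degenerate")
})

test_that("inflow profile is the stated parabola with flux 20 f / 3", {
  expect_equal(inflow_profile(1.5, 5), 1.5)
  expect_equal(inflow_profile(3.7, 0), 0)
  expect_equal(inflow_profile(3.7, 10), 0)
  expect_equal(inflow_profile(2, 2.5), 1.5)
  q <- integrate(function(y) inflow_profile(1.5, y), 0, 10)$value
  expect_equal(q, 20 * 1.5 / 3, tolerance = 1e-8)
  expect_error(inflow_profile(1, -0.1), "within")
})

test_that("mesh generation is deterministic with valid topology and tags", {
  m <- generate_mesh(tube_geometry(-1.5), 300)
  expect_true(abs(nrow(m$p1$nodes) - 300) / 300 < 0.25)
  expect_true(all(vastra:::signed_area2(m$p1$nodes, m$p1$tri) > 0))

  # tag partition: each node exactly one tag, boundary tags complete
  expect_true(all(m$p1$tag %in% c("interior", "wall", "inflow", "outflow")))
  infl <- m$p1$tag == "inflow"
  expect_true(all(m$p1$nodes[infl, 1] == 0))
  expect_true(all(m$p1$nodes[m$p1$tag == "outflow", 1] == 100))
  wall <- m$p1$tag == "wall"
  hx <- wall_halfwidth(m$p1$nodes[wall, 1], -1.5)
  expect_lt(max(abs(abs(m$p1$nodes[wall, 2] - 5) - hx)), 1e-9)

  # every x = 0 or x = 100 non-wall node is tagged; interior nodes are not
  # on the boundary
  inter <- m$p1$tag == "interior"
  expect_true(all(m$p1$nodes[inter, 1] > 0 & m$p1$nodes[inter, 1] < 100))

  m2 <- generate_mesh(tube_geometry(-1.5), 300)
  expect_identical(m$p1, m2$p1)
  expect_identical(m$p2$tri6, m2$p2$tri6)

  # throat gap of the r = -2 tube is 6 mm
  m3 <- generate_mesh(tube_geometry(-2), 300)
  throat <- m3$p1$nodes[abs(m3$p1$nodes[, 1] - 50) < 1e-9, 2]
  expect_equal(max(throat) - min(throat), 6)

  expect_error(generate_mesh(tube_geometry(0), 20), "at least")
})

test_that("point location and linear interpolation are exact for linear fields", {
  m <- generate_mesh(tube_geometry(-1), 300)
  vals <- 2 + 0.3 * m$p1$nodes[, 1] - 1.7 * m$p1$nodes[, 2]
  pts <- cbind(c(5, 50, 95, 0.01, 99.99), c(5, 3.3, 6.1, 5, 5))
  got <- interp_vertex_field(m, vals, pts)
  expect_equal(got, 2 + 0.3 * pts[, 1] - 1.7 * pts[, 2], tolerance = 1e-10)
  expect_error(locate_points(m, cbind(50, 20)), "outside")
  expect_error(locate_points(m, cbind(-5, 5)), "outside")
})

test_that("VTK writer and reader round-trip the mesh and nodal fields", {
  m <- generate_mesh(tube_geometry(0.7), 200)
  path <- tempfile(fileext = ".vtk")
  pdata <- list(pressure = rnorm(nrow(m$p1$nodes)),
                velocity = cbind(rnorm(nrow(m$p1$nodes)),
                                 rnorm(nrow(m$p1$nodes))))
  write_mesh_vtk(m, path, pdata)
  back <- read_mesh_vtk(path)
  expect_equal(unname(back$nodes), unname(m$p1$nodes))
  expect_equal(back$tri, unname(m$p1$tri))
  expect_equal(back$meta$r, 0.7)
  expect_equal(back$point_data$pressure, pdata$pressure)
  expect_equal(back$point_data$velocity, pdata$velocity)
})
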