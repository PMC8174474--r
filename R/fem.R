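#' Fluid properties
#'
#' Density and dynamic viscosity in the g/mm/s unit system (pressure then
#' comes out in g mm^-1 s^-2, which equals Pa). Defaults are representative
#' of blood.
#'
#' @param rho density in g/mm^3.
#' @param mu dynamic viscosity in g/(mm s).
#' @return list of class \code{fluid_properties}.
#' @export
fluid_properties <- function(rho = 0.00106, mu = 0.004) {
  stopifnot(is.numeric(rho), rho > 0, is.numeric(mu), mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

# --- reference-element tables -------------------------------------------

# 7-point, degree-5 Gauss rule on the reference triangle; weights sum to 1/2.
tri_quadrature <- function() {
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  lam <- rbind(
    c(1/3, 1/3, 1/3),
    c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
    c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2)
  )
  w <- c(0.225,
         rep(0.132394152788506, 3),
         rep(0.125939180544827, 3)) / 2
  list(lambda = lam, w = w)
}

# quadratic (6-node) basis values and reference gradients at quadrature pts
p2_basis <- function(quad) {
  nq <- nrow(quad$lambda)
  N <- matrix(0, 6, nq); dXi <- matrix(0, 6, nq); dEta <- matrix(0, 6, nq)
  for (q in seq_len(nq)) {
    l <- quad$lambda[q, ]
    g <- rbind(c(-1, -1), c(1, 0), c(0, 1))  # grad of barycentric coords
    N[1:3, q] <- l * (2 * l - 1)
    N[4, q] <- 4 * l[1] * l[2]
    N[5, q] <- 4 * l[2] * l[3]
    N[6, q] <- 4 * l[3] * l[1]
    for (i in 1:3) {
      dXi[i, q] <- (4 * l[i] - 1) * g[i, 1]
      dEta[i, q] <- (4 * l[i] - 1) * g[i, 2]
    }
    dXi[4, q] <- 4 * (l[2] * g[1, 1] + l[1] * g[2, 1])
    dEta[4, q] <- 4 * (l[2] * g[1, 2] + l[1] * g[2, 2])
    dXi[5, q] <- 4 * (l[3] * g[2, 1] + l[2] * g[3, 1])
    dEta[5, q] <- 4 * (l[3] * g[2, 2] + l[2] * g[3, 2])
    dXi[6, q] <- 4 * (l[3] * g[1, 1] + l[1] * g[3, 1])
    dEta[6, q] <- 4 * (l[3] * g[1, 2] + l[1] * g[3, 2])
  }
  list(N = N, dXi = dXi, dEta = dEta)
}

# per-element geometry and physical basis gradients, shared by all assemblies
fem_precompute <- function(mesh) {
  quad <- tri_quadrature()
  basis <- p2_basis(quad)
  tri <- mesh$p1$tri; tri6 <- mesh$p2$tri6
  nodes <- mesh$p1$nodes
  ne <- nrow(tri); nq <- length(quad$w)
  j11 <- nodes[tri[, 2], 1] - nodes[tri[, 1], 1]
  j21 <- nodes[tri[, 2], 2] - nodes[tri[, 1], 2]
  j12 <- nodes[tri[, 3], 1] - nodes[tri[, 1], 1]
  j22 <- nodes[tri[, 3], 2] - nodes[tri[, 1], 2]
  det <- j11 * j22 - j12 * j21
  GX <- array(0, c(ne, 6, nq)); GY <- array(0, c(ne, 6, nq))
  for (a in 1:6) for (q in 1:nq) {
    GX[, a, q] <- (j22 * basis$dXi[a, q] - j21 * basis$dEta[a, q]) / det
    GY[, a, q] <- (-j12 * basis$dXi[a, q] + j11 * basis$dEta[a, q]) / det
  }
  lamq <- t(quad$lambda)  # 3 x nq, P1 basis values
  list(quad = quad, basis = basis, GX = GX, GY = GY, det = det,
       tri = tri, tri6 = tri6, ne = ne, nq = nq, lam = lamq,
       np1 = nrow(mesh$p1$nodes), np2 = nrow(mesh$p2$nodes))
}

# constant sparse operators: viscous stiffness (P2), pressure-gradient
# coupling Gx, Gy (rows P2 velocity, cols P1 pressure)
fem_operators <- function(pc) {
  w <- pc$quad$w; N <- pc$basis$N
  iK <- jK <- xK <- vector("list", 36)
  iG <- jG <- xGx <- xGy <- vector("list", 18)
  k <- 0
  for (a in 1:6) for (b in 1:6) {
    k <- k + 1
    val <- numeric(pc$ne)
    for (q in 1:pc$nq)
      val <- val + w[q] * (pc$GX[, a, q] * pc$GX[, b, q] +
                           pc$GY[, a, q] * pc$GY[, b, q])
    iK[[k]] <- pc$tri6[, a]; jK[[k]] <- pc$tri6[, b]; xK[[k]] <- val * pc$det
  }
  k <- 0
  for (a in 1:6) for (c in 1:3) {
    k <- k + 1
    vx <- vy <- numeric(pc$ne)
    for (q in 1:pc$nq) {
      vx <- vx + w[q] * pc$GX[, a, q] * pc$lam[c, q]
      vy <- vy + w[q] * pc$GY[, a, q] * pc$lam[c, q]
    }
    iG[[k]] <- pc$tri6[, a]; jG[[k]] <- pc$tri[, c]
    xGx[[k]] <- vx * pc$det; xGy[[k]] <- vy * pc$det
  }
  K <- Matrix::sparseMatrix(i = unlist(iK), j = unlist(jK), x = unlist(xK),
                            dims = c(pc$np2, pc$np2))
  Gx <- Matrix::sparseMatrix(i = unlist(iG), j = unlist(jG), x = unlist(xGx),
                             dims = c(pc$np2, pc$np1))
  Gy <- Matrix::sparseMatrix(i = unlist(iG), j = unlist(jG), x = unlist(xGy),
                             dims = c(pc$np2, pc$np1))
  list(K = K, Gx = Gx, Gy = Gy)
}

# velocity and velocity-gradient values at quadrature points (ne x nq each)
fields_at_quad <- function(pc, ux, uy) {
  ne <- pc$ne; nq <- pc$nq
  UX <- matrix(ux[pc$tri6], ne, 6); UY <- matrix(uy[pc$tri6], ne, 6)
  out <- list(ux = matrix(0, ne, nq), uy = matrix(0, ne, nq),
              uxx = matrix(0, ne, nq), uxy = matrix(0, ne, nq),
              uyx = matrix(0, ne, nq), uyy = matrix(0, ne, nq))
  N <- pc$basis$N
  for (q in 1:nq) {
    for (a in 1:6) {
      out$ux[, q] <- out$ux[, q] + N[a, q] * UX[, a]
      out$uy[, q] <- out$uy[, q] + N[a, q] * UY[, a]
      out$uxx[, q] <- out$uxx[, q] + pc$GX[, a, q] * UX[, a]
      out$uxy[, q] <- out$uxy[, q] + pc$GY[, a, q] * UX[, a]
      out$uyx[, q] <- out$uyx[, q] + pc$GX[, a, q] * UY[, a]
      out$uyy[, q] <- out$uyy[, q] + pc$GY[, a, q] * UY[, a]
    }
  }
  out
}

# convective residual vector (length 2*np2) for given velocity
convective_residual <- function(pc, fq, rho) {
  w <- pc$quad$w; N <- pc$basis$N
  rx <- numeric(pc$np2); ry <- numeric(pc$np2)
  convx <- fq$ux * fq$uxx + fq$uy * fq$uxy  # (u . grad) u_x at quad pts
  convy <- fq$ux * fq$uyx + fq$uy * fq$uyy
  for (a in 1:6) {
    accx <- numeric(pc$ne); accy <- numeric(pc$ne)
    for (q in 1:pc$nq) {
      accx <- accx + w[q] * N[a, q] * convx[, q]
      accy <- accy + w[q] * N[a, q] * convy[, q]
    }
    idx <- pc$tri6[, a]
    rx <- rx + unname(tapply_add(idx, rho * accx * pc$det, pc$np2))
    ry <- ry + unname(tapply_add(idx, rho * accy * pc$det, pc$np2))
  }
  c(rx, ry)
}

tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# triplets of the convective Newton-Jacobian blocks
convective_jacobian_triplets <- function(pc, fq, rho) {
  w <- pc$quad$w; N <- pc$basis$N
  n <- 36 * pc$ne
  i <- integer(n); j <- integer(n)
  xx <- numeric(n); xy <- numeric(n); yx <- numeric(n); yy <- numeric(n)
  k <- 0
  for (a in 1:6) for (b in 1:6) {
    vxx <- vxy <- vyx <- vyy <- numeric(pc$ne)
    for (q in 1:pc$nq) {
      adv <- fq$ux[, q] * pc$GX[, b, q] + fq$uy[, q] * pc$GY[, b, q]
      Nab <- N[a, q] * N[b, q]
      vxx <- vxx + w[q] * (N[a, q] * adv + Nab * fq$uxx[, q])
      vxy <- vxy + w[q] * Nab * fq$uxy[, q]
      vyx <- vyx + w[q] * Nab * fq$uyx[, q]
      vyy <- vyy + w[q] * (N[a, q] * adv + Nab * fq$uyy[, q])
    }
    rng <- (k * pc$ne + 1):((k + 1) * pc$ne); k <- k + 1
    i[rng] <- pc$tri6[, a]; j[rng] <- pc$tri6[, b]
    xx[rng] <- rho * vxx * pc$det; xy[rng] <- rho * vxy * pc$det
    yx[rng] <- rho * vyx * pc$det; yy[rng] <- rho * vyy * pc$det
  }
  list(i = i, j = j, xx = xx, xy = xy, yx = yx, yy = yy)
}

dirichlet_data <- function(mesh, f) {
  tag <- mesh$p2$tag
  d <- which(tag %in% c("wall", "inflow"))
  gx <- numeric(length(d)); gy <- numeric(length(d))
  infl <- tag[d] == "inflow"
  gx[infl] <- inflow_profile(f, mesh$p2$nodes[d[infl], 2])
  list(idx = d, gx = gx, gy = gy)
}

# assemble the full Jacobian with Dirichlet rows replaced by the identity
assemble_system <- function(pc, ops, mu, conv_trip, dir_rows) {
  np2 <- pc$np2; np1 <- pc$np1
  Kt <- Matrix::mat2triplet(ops$K)
  Gxt <- Matrix::mat2triplet(ops$Gx)
  Gyt <- Matrix::mat2triplet(ops$Gy)
  i <- c(Kt$i, Kt$i + np2,                              # viscous blocks
         Gxt$i, Gyt$i + np2,                            # -G p in momentum
         Gxt$j + 2L * np2, Gyt$j + 2L * np2)            # continuity D u
  j <- c(Kt$j, Kt$j + np2,
         Gxt$j + 2L * np2, Gyt$j + 2L * np2,
         Gxt$i, Gyt$i + np2)
  x <- c(mu * Kt$x, mu * Kt$x, -Gxt$x, -Gyt$x, Gxt$x, Gyt$x)
  if (!is.null(conv_trip)) {
    i <- c(i, conv_trip$i, conv_trip$i, conv_trip$i + np2, conv_trip$i + np2)
    j <- c(j, conv_trip$j, conv_trip$j + np2, conv_trip$j, conv_trip$j + np2)
    x <- c(x, conv_trip$xx, conv_trip$xy, conv_trip$yx, conv_trip$yy)
  }
  keep <- !(i %in% dir_rows)
  i <- c(i[keep], dir_rows); j <- c(j[keep], dir_rows)
  x <- c(x[keep], rep(1, length(dir_rows)))
  n <- 2L * np2 + np1
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

fem_residual <- function(pc, ops, mu, rho, ux, uy, p, dir_rows, with_conv = TRUE) {
  fx <- as.numeric(mu * (ops$K %*% ux) - ops$Gx %*% p)
  fy <- as.numeric(mu * (ops$K %*% uy) - ops$Gy %*% p)
  fc <- as.numeric(Matrix::t(ops$Gx) %*% ux + Matrix::t(ops$Gy) %*% uy)
  Fv <- c(fx, fy, fc)
  if (with_conv) {
    fq <- fields_at_quad(pc, ux, uy)
    Fv[seq_len(2 * pc$np2)] <- Fv[seq_len(2 * pc$np2)] +
      convective_residual(pc, fq, rho)
    attr(Fv, "fq") <- fq
  }
  Fv[dir_rows] <- 0  # Dirichlet dofs are held exactly
  Fv
}

#' Solve the linear Stokes problem on a tube mesh
#'
#' Taylor-Hood (quadratic velocity, linear pressure) discretisation of
#' steady Stokes flow with the parabolic inflow, no-slip walls and a
#' do-nothing outflow that fixes the pressure gauge. Used as the initial
#' guess for the Newton iteration of the nonlinear solver.
#'
#' @param mesh a \code{\link{generate_mesh}} result.
#' @param theta list or vector with components \code{f} and \code{r} (r must
#'   match the meshed geometry).
#' @param props \code{\link{fluid_properties}}.
#' @return A \code{fem_solution}: velocities \code{ux}, \code{uy} on
#'   quadratic nodes, pressure \code{p} on vertex nodes, plus convergence
#'   metadata.
#' @export
solve_stokes <- function(mesh, theta, props = fluid_properties()) {
  theta <- check_theta(theta, mesh)
  pc <- fem_precompute(mesh)
  ops <- fem_operators(pc)
  dir <- dirichlet_data(mesh, theta$f)
  dir_rows <- c(dir$idx, dir$idx + pc$np2)
  np2 <- pc$np2; np1 <- pc$np1
  U <- numeric(2 * np2 + np1)
  U[dir$idx] <- dir$gx; U[dir$idx + np2] <- dir$gy
  Fv <- fem_residual(pc, ops, props$mu, props$rho,
                     U[1:np2], U[np2 + 1:np2], U[2 * np2 + 1:np1],
                     dir_rows, with_conv = FALSE)
  A <- assemble_system(pc, ops, props$mu, NULL, dir_rows)
  delta <- tryCatch(Matrix::solve(A, -Fv),
                    error = function(e) stop("Stokes system is singular: ",
                                             conditionMessage(e)))
  U <- U + as.numeric(delta)
  new_fem_solution(mesh, theta, props, U, pc,
                   history = numeric(0), converged = TRUE,
                   label = "stokes")
}

#' Solve steady incompressible Navier-Stokes on a tube mesh
#'
#' Newton iteration on the Taylor-Hood discretisation of
#' rho (u . grad) u - mu lap(u) = -grad p, div u = 0, starting from the
#' Stokes solution. Boundary conditions: u = (I_f(y), 0) on the inflow,
#' u = 0 on the walls (both imposed exactly by row elimination), and a
#' natural do-nothing outflow.
#'
#' @inheritParams solve_stokes
#' @param tol absolute tolerance on the max-norm of the nonlinear residual.
#' @param max_newton maximum Newton iterations.
#' @return A \code{fem_solution} with the Newton residual history in
#'   \code{$newton} and \code{$converged}.
#' @export
solve_navier_stokes <- function(mesh, theta, props = fluid_properties(),
                                tol = 1e-10, max_newton = 25) {
  stopifnot(tol > 0)
  theta <- check_theta(theta, mesh)
  pc <- fem_precompute(mesh)
  ops <- fem_operators(pc)
  dir <- dirichlet_data(mesh, theta$f)
  dir_rows <- c(dir$idx, dir$idx + pc$np2)
  np2 <- pc$np2; np1 <- pc$np1

  sol0 <- solve_stokes(mesh, theta, props)
  U <- c(sol0$ux, sol0$uy, sol0$p)
  history <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_newton)) {
    Fv <- fem_residual(pc, ops, props$mu, props$rho,
                       U[1:np2], U[np2 + 1:np2], U[2 * np2 + 1:np1], dir_rows)
    res <- max(abs(Fv))
    history <- c(history, res)
    if (res <= tol) { converged <- TRUE; break }
    fq <- attr(Fv, "fq")
    trip <- convective_jacobian_triplets(pc, fq, props$rho)
    A <- assemble_system(pc, ops, props$mu, trip, dir_rows)
    delta <- Matrix::solve(A, -as.numeric(Fv))
    U <- U + as.numeric(delta)
  }
  if (!converged) {
    # residual after the final update
    Fv <- fem_residual(pc, ops, props$mu, props$rho,
                       U[1:np2], U[np2 + 1:np2], U[2 * np2 + 1:np1], dir_rows)
    res <- max(abs(Fv))
    history <- c(history, res)
    converged <- res <= tol
    if (!converged)
      stop("Newton did not converge within ", max_newton,
           " iterations; residual history: ",
           paste(signif(history, 3), collapse = ", "))
  }
  new_fem_solution(mesh, theta, props, U, pc, history = history,
                   converged = converged, label = "navier-stokes")
}

check_theta <- function(theta, mesh = NULL) {
  theta <- as.list(theta)
  stopifnot(all(c("f", "r") %in% names(theta)),
            is.finite(theta$f), is.finite(theta$r))
  if (!is.null(mesh) && abs(theta$r - mesh$geom$r) > 1e-12)
    stop("theta$r = ", theta$r, " does not match the meshed geometry r = ",
         mesh$geom$r)
  theta[c("f", "r")]
}

new_fem_solution <- function(mesh, theta, props, U, pc, history, converged,
                             label) {
  np2 <- pc$np2; np1 <- pc$np1
  structure(
    list(mesh = mesh, theta = theta, props = props,
         ux = U[1:np2], uy = U[np2 + 1:np2], p = U[2 * np2 + 1:np1],
         newton = history, converged = converged, method = label),
    class = "fem_solution"
  )
}

#' @exportS3Method base::print
print.fem_solution <- function(x, ...) {
  cat(sprintf("%s solution at (f = %g, r = %g): %d velocity nodes, %d pressure nodes\n",
              x$method, x$theta$f, x$theta$r, length(x$ux), length(x$p)))
  if (length(x$newton))
    cat(sprintf("  Newton: %d steps, final residual %.3g\n",
                length(x$newton), tail(x$newton, 1)))
  invisible(x)
}

#' Pressure difference between two probe points
#'
#' Interpolates the linear-basis pressure field at two points and returns
#' p(a) - p(b).
#'
#' @param sol a \code{fem_solution}.
#' @param point_a,point_b numeric (x, y) in mm; must lie inside the domain.
#' @return pressure difference in Pa.
#' @export
probe_pressure <- function(sol, point_a, point_b) {
  vals <- interp_vertex_field(sol$mesh, sol$p, rbind(point_a, point_b))
  vals[1] - vals[2]
}

#' Boundary volume flux
#'
#' Integral of u . n over the inflow or outflow boundary (outward normal),
#' by edge-wise Simpson quadrature, exact for the quadratic trace.
#'
#' @param sol a \code{fem_solution}.
#' @param segment \code{"inflow"} or \code{"outflow"}.
#' @return signed flux in mm^2/s.
#' @export
boundary_flux <- function(sol, segment = c("inflow", "outflow")) {
  segment <- match.arg(segment)
  edges <- if (segment == "inflow") sol$mesh$inflow_edges else sol$mesh$outflow_edges
  y <- sol$mesh$p2$nodes[, 2]
  sgn <- if (segment == "inflow") -1 else 1  # outward normal is -x / +x
  dy <- y[edges[, 3]] - y[edges[, 1]]
  u <- matrix(sol$ux[edges], nrow(edges), 3)
  sum(sgn * dy / 6 * (u[, 1] + 4 * u[, 2] + u[, 3]))
}

#' Mass-conservation check
#'
#' Relative mismatch of the inflow and outflow volume fluxes,
#' |flux_in + flux_out| / |flux_in|.
#'
#' @param sol a converged \code{fem_solution}.
#' @return non-negative scalar; small for a converged incompressible
#'   solution. Errors if the inflow flux vanishes while f != 0.
#' @export
flux_balance <- function(sol) {
  fin <- boundary_flux(sol, "inflow")
  fout <- boundary_flux(sol, "outflow")
  if (abs(fin) < 1e-14) {
    if (abs(sol$theta$f) > 0)
      stop("inflow flux is zero although f = ", sol$theta$f)
    return(abs(fout))
  }
  abs(fin + fout) / abs(fin)
}

#' Write a FEM solution as legacy-ASCII VTK
#'
#' Writes the vertex mesh with nodal pressure and velocity point data
#' (velocity restricted to vertex nodes).
#'
#' @param sol a \code{fem_solution}.
#' @param path output path.
#' @export
write_solution_vtk <- function(sol, path) {
  mesh <- sol$mesh
  v1 <- p2_vertex_values(mesh)
  write_mesh_vtk(mesh, path, point_data = list(
    pressure = sol$p,
    velocity = cbind(sol$ux[v1], sol$uy[v1])
  ))
}

# indices of the vertex (P1) nodes within the quadratic node numbering
p2_vertex_values <- function(mesh) {
  nb <- 2L * mesh$ny
  i <- rep(0:mesh$nx, each = mesh$ny + 1L)
  j <- rep(0:mesh$ny, times = mesh$nx + 1L)
  idx_grid(2L * i, 2L * j, nb + 1L)
}
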