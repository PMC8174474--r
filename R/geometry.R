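#' Parametric tube geometry
#'
#' The flow domain is a tube of length 100 mm whose ends are 10 mm wide.
#' A single shape parameter \code{r} deforms both walls symmetrically about
#' the midline y = 5 mm: the local half-width is
#' \deqn{h(x; r) = 5 + r \cos^2(\pi (x - 50) / 100),}
#' so negative \code{r} narrows the tube (a stenosis), positive \code{r}
#' bulges it outwards, and \code{r = 0} recovers the straight tube exactly.
#' The end widths are exact for every \code{r} and the wall leaves both ends
#' with zero slope.
#'
#' @param r dimensionless shape parameter; the tube degenerates (zero gap)
#'   at \code{r = -5}, and values in \[-2, 2\] are the intended design range.
#' @return An object of class \code{tube_geometry} with fields \code{r},
#'   \code{length} (100 mm), \code{end_width} (10 mm) and \code{halfwidth},
#'   a vectorised function of x.
#' @export
#' @examples
#' geom <- tube_geometry(-2)
#' geom$halfwidth(50)  # 3 mm: a 6 mm gap at the throat
tube_geometry <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  L <- 100
  if (min_halfwidth(r) <= 0)
    stop("degenerate geometry: halfwidth h(x; r) <= 0 for r = ", r)
  structure(
    list(
      r = r, length = L, end_width = 10, midline = 5,
      halfwidth = function(x) wall_halfwidth(x, r)
    ),
    class = "tube_geometry"
  )
}

min_halfwidth <- function(r) if (r < 0) 5 + r else 5

#' Tube half-width at a station
#'
#' Half the local wall-to-wall distance of the parametric tube,
#' \code{5 + r * cos(pi * (x - 50) / 100)^2} mm.
#'
#' @param x axial position in mm, in \[0, 100\]; vectorised.
#' @param r shape parameter.
#' @return Half-width in mm.
#' @export
wall_halfwidth <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r))
  if (any(!is.finite(x)) || any(x < 0 | x > 100))
    stop("x must lie within the tube, [0, 100] mm")
  5 + r * cos(pi * (x - 50) / 100)^2
}

#' Parabolic inflow velocity profile
#'
#' Axial inflow velocity imposed on the x = 0 boundary,
#' \code{I_f(y) = f * y * (10 - y) / 25}, peaking at \code{f} mm/s on the
#' midline y = 5 and vanishing at the walls. The y-component of the imposed
#' velocity is zero. Closed-form flux: \code{integral(I_f) = 20 f / 3}.
#'
#' @param f peak inflow velocity in mm/s (may be negative: reversed flow).
#' @param y transverse position in mm, in \[0, 10\]; vectorised.
#' @return x-velocity in mm/s.
#' @export
inflow_profile <- function(f, y) {
  stopifnot(is.numeric(f), is.numeric(y))
  if (any(!is.finite(y)) || any(y < 0 | y > 10))
    stop("y must lie within the inflow boundary, [0, 10] mm")
  f * y * (10 - y) / 25
}

#' Build the parameter grid G
#'
#' Discretises a rectangular region of the (f, r) design space with a
#' uniform spacing. Points are ordered row-major with r varying fastest:
#' the first point is (f_min, r_min), then r increases, then f advances.
#'
#' @param region list with numeric ranges \code{f = c(min, max)} and
#'   \code{r = c(min, max)}.
#' @param spacing grid spacing, must divide both extents.
#' @return Object of class \code{parameter_grid}: \code{f_values},
#'   \code{r_values}, \code{points} (data.frame of f, r in row-major order),
#'   and \code{region}.
#' @export
#' @examples
#' g <- build_grid(design_region(), 1/3)
#' nrow(g$points)  # 169 = 13 x 13
build_grid <- function(region, spacing) {
  region <- check_region(region)
  stopifnot(is.numeric(spacing), length(spacing) == 1L)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  vals <- function(rng) {
    n <- (rng[2] - rng[1]) / spacing
    if (abs(n - round(n)) > 1e-9)
      stop("spacing ", spacing, " does not divide the extent [",
           rng[1], ", ", rng[2], "]")
    rng[1] + spacing * seq(0L, round(n))
  }
  f_values <- vals(region$f)
  r_values <- vals(region$r)
  pts <- expand.grid(r = r_values, f = f_values,
                     KEEP.OUT.ATTRS = FALSE)[, c("f", "r")]
  rownames(pts) <- NULL
  structure(
    list(f_values = f_values, r_values = r_values,
         points = pts, region = region, spacing = spacing),
    class = "parameter_grid"
  )
}

#' @exportS3Method base::print
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter grid: %d x %d = %d points, f in [%g, %g], r in [%g, %g]\n",
              length(x$f_values), length(x$r_values), nrow(x$points),
              min(x$f_values), max(x$f_values),
              min(x$r_values), max(x$r_values)))
  invisible(x)
}

#' Default design region
#'
#' The square region \code{f, r} in \[-2, 2\] over which the surrogate is
#' trained.
#' @return list with ranges \code{f} and \code{r}.
#' @export
design_region <- function() list(f = c(-2, 2), r = c(-2, 2))

check_region <- function(region) {
  stopifnot(is.list(region), all(c("f", "r") %in% names(region)))
  for (k in c("f", "r")) {
    v <- region[[k]]
    stopifnot(is.numeric(v), length(v) == 2L, all(is.finite(v)), v[1] <= v[2])
  }
  region[c("f", "r")]
}

#' Corners-and-centre initialisation points
#'
#' The five seed locations of the learning loop: the four corners of the
#' design region plus its centre, deduplicated for degenerate regions.
#'
#' @inheritParams build_grid
#' @return data.frame of f, r in deterministic order (corners with r varying
#'   fastest, then the centre).
#' @export
corners_and_centre <- function(region) {
  region <- check_region(region)
  f <- region$f; r <- region$r
  pts <- data.frame(
    f = c(f[1], f[1], f[2], f[2], mean(f)),
    r = c(r[1], r[2], r[1], r[2], mean(r))
  )
  unique(pts)
}

#' Uniform sub-grid baseline points
#'
#' The coarse uniform sub-grid used by the uniform sampling baseline;
#' with the default region and step 1 this is f, r in \{-2, -1, 0, 1, 2\}
#' (25 points). The sweep order advances r fastest: all values of r for
#' the current f are exhausted before f is incremented.
#'
#' @inheritParams build_grid
#' @param step sub-grid step, must divide both extents.
#' @return data.frame of f, r in sweep order.
#' @export
uniform_subgrid <- function(region, step = 1) {
  g <- build_grid(region, step)
  g$points
}

# Mesh node numbering: P1 vertices live on the (nx+1) x (ny+1) corner grid,
# P2 nodes on the refined (2nx+1) x (2ny+1) grid; both are numbered with the
# transverse index fastest.  idx(i, j) is 1-based.
idx_grid <- function(i, j, nj) i * nj + j + 1L

#' Generate a structured triangle mesh of a tube
#'
#' Maps a structured triangulation of the parametric strip
#' (xi in \[0, 100\], eta in \[-1, 1\]) onto the physical tube through
#' y = 5 + eta * h(xi; r). Each rectangular cell is split into two
#' triangles along the (+,+) diagonal. Quadratic (Taylor-Hood velocity)
#' nodes are the refined-grid points, placed at straight-edge midpoints so
#' elements are affine. Determinism: identical connectivity and coordinates
#' on repeated calls with the same arguments.
#'
#' @param geom a \code{\link{tube_geometry}}.
#' @param target_nodes requested number of linear (vertex) nodes; the
#'   generated count is within 25\% of this. Must be >= 50.
#' @return Object of class \code{tube_mesh} with components \code{p1}
#'   (vertex \code{nodes}, \code{tri}, boundary \code{tag}) and \code{p2}
#'   (quadratic \code{nodes}, \code{tri6}, \code{tag}), plus inflow/outflow
#'   edge lists for boundary quadrature. Tags partition the boundary into
#'   wall, inflow, outflow (corners count as wall); interior nodes are
#'   tagged interior.
#' @export
generate_mesh <- function(geom, target_nodes = 1000) {
  stopifnot(inherits(geom, "tube_geometry"))
  if (!is.numeric(target_nodes) || target_nodes < 50)
    stop("target_nodes must be at least 50")
  L <- geom$length
  aspect <- L / geom$end_width
  # ny is forced even and the cell diagonals are mirrored about the midline,
  # so the triangulation (and hence the discrete solution) is exactly
  # symmetric under y -> 10 - y
  ny <- max(2L, 2L * as.integer(round(sqrt(target_nodes / aspect) / 2)))
  nx <- max(4L, as.integer(round(target_nodes / (ny + 1))) - 1L)

  # refined grid (P2): indices a = 0..2nx, b = 0..2ny
  na <- 2L * nx; nb <- 2L * ny
  xi <- L * (0:na) / na
  h <- geom$halfwidth(xi)
  if (any(h <= 0)) stop("degenerate geometry: halfwidth <= 0")
  eta <- -1 + 2 * (0:nb) / nb

  a_id <- rep(0:na, each = nb + 1L)
  b_id <- rep(0:nb, times = na + 1L)
  x2 <- xi[a_id + 1L]
  y2 <- 5 + eta[b_id + 1L] * h[a_id + 1L]
  # straight-sided elements: non-vertex nodes sit at edge midpoints
  vert <- function(a, b) cbind(xi[a + 1L], 5 + eta[b + 1L] * h[a + 1L])
  odd_a <- (a_id %% 2L == 1L) & (b_id %% 2L == 0L)
  odd_b <- (a_id %% 2L == 0L) & (b_id %% 2L == 1L)
  odd_ab <- (a_id %% 2L == 1L) & (b_id %% 2L == 1L)
  mid <- function(p, q) (p + q) / 2
  if (any(odd_a)) {
    m <- mid(vert(a_id[odd_a] - 1L, b_id[odd_a]), vert(a_id[odd_a] + 1L, b_id[odd_a]))
    x2[odd_a] <- m[, 1]; y2[odd_a] <- m[, 2]
  }
  if (any(odd_b)) {
    m <- mid(vert(a_id[odd_b], b_id[odd_b] - 1L), vert(a_id[odd_b], b_id[odd_b] + 1L))
    x2[odd_b] <- m[, 1]; y2[odd_b] <- m[, 2]
  }
  if (any(odd_ab)) {
    # cell-centre node: midpoint of the cell diagonal, whose direction is
    # mirrored between the lower and upper halves of the tube
    lower <- (b_id[odd_ab] - 1L) / 2L < ny %/% 2L
    am <- a_id[odd_ab]; bm <- b_id[odd_ab]
    m <- matrix(0, length(am), 2)
    if (any(lower))
      m[lower, ] <- mid(vert(am[lower] - 1L, bm[lower] - 1L),
                        vert(am[lower] + 1L, bm[lower] + 1L))
    if (any(!lower))
      m[!lower, ] <- mid(vert(am[!lower] + 1L, bm[!lower] - 1L),
                         vert(am[!lower] - 1L, bm[!lower] + 1L))
    x2[odd_ab] <- m[, 1]; y2[odd_ab] <- m[, 2]
  }
  nodes2 <- cbind(x = x2, y = y2)

  tag_of <- function(a, b, amax, bmax) {
    ifelse(b == 0L | b == bmax, "wall",
           ifelse(a == 0L, "inflow",
                  ifelse(a == amax, "outflow", "interior")))
  }
  tag2 <- tag_of(a_id, b_id, na, nb)

  # P1 view: even-even refined nodes
  i_id <- rep(0:nx, each = ny + 1L)
  j_id <- rep(0:ny, times = nx + 1L)
  p1_in_p2 <- idx_grid(2L * i_id, 2L * j_id, nb + 1L)
  nodes1 <- nodes2[p1_in_p2, , drop = FALSE]
  tag1 <- tag2[p1_in_p2]

  # connectivity; lower-half cells use the (v00, v11) diagonal, upper-half
  # cells its mirror image (v10, v01)
  i <- rep(0:(nx - 1L), each = ny)
  j <- rep(0:(ny - 1L), times = nx)
  low <- j < ny %/% 2L
  v00 <- idx_grid(i, j, ny + 1L)
  v10 <- idx_grid(i + 1L, j, ny + 1L)
  v11 <- idx_grid(i + 1L, j + 1L, ny + 1L)
  v01 <- idx_grid(i, j + 1L, ny + 1L)
  t1 <- cbind(v00, v10, ifelse(low, v11, v01))
  t2 <- cbind(ifelse(low, v00, v10), v11, v01)
  tri <- rbind(t1, t2)

  q2 <- function(a, b) idx_grid(a, b, nb + 1L)
  A <- 2L * i; B <- 2L * j
  pick <- function(lo, hi) ifelse(low, lo, hi)
  t1m <- cbind(q2(A + 1L, B),
               pick(q2(A + 2L, B + 1L), q2(A + 1L, B + 1L)),
               pick(q2(A + 1L, B + 1L), q2(A, B + 1L)))
  t2m <- cbind(pick(q2(A + 1L, B + 1L), q2(A + 2L, B + 1L)),
               q2(A + 1L, B + 2L),
               pick(q2(A, B + 1L), q2(A + 1L, B + 1L)))
  tri6 <- rbind(
    cbind(q2(A, B), q2(A + 2L, B), pick(q2(A + 2L, B + 2L), q2(A, B + 2L)), t1m),
    cbind(pick(q2(A, B), q2(A + 2L, B)), q2(A + 2L, B + 2L), q2(A, B + 2L), t2m)
  )

  area2 <- signed_area2(nodes1, tri)
  if (any(area2 <= 0)) stop("mesh generation produced non-positive triangle areas")

  # boundary edge lists on the P2 grid (end, mid, end), for flux quadrature
  edge_list <- function(a) {
    b0 <- seq(0L, nb - 2L, by = 2L)
    cbind(q2(rep(a, length(b0)), b0),
          q2(rep(a, length(b0)), b0 + 1L),
          q2(rep(a, length(b0)), b0 + 2L))
  }

  structure(
    list(
      geom = geom, nx = nx, ny = ny,
      p1 = list(nodes = nodes1, tri = tri, tag = tag1),
      p2 = list(nodes = nodes2, tri6 = tri6, tag = tag2),
      inflow_edges = edge_list(0L), outflow_edges = edge_list(na)
    ),
    class = "tube_mesh"
  )
}

#' @exportS3Method base::print
print.tube_mesh <- function(x, ...) {
  cat(sprintf("tube mesh: r = %g, %d vertex nodes, %d quadratic nodes, %d triangles\n",
              x$geom$r, nrow(x$p1$nodes), nrow(x$p2$nodes), nrow(x$p1$tri)))
  invisible(x)
}

# twice the signed triangle areas
signed_area2 <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
}

#' Locate points in a mesh
#'
#' Finds, for each query point, the containing vertex triangle and its
#' barycentric coordinates. The structured parametric layout gives the
#' candidate cell directly; neighbouring cells are checked to absorb the
#' mild distortion of the mapping.
#'
#' @param mesh a \code{tube_mesh}.
#' @param pts n x 2 matrix of (x, y) in mm.
#' @return list with integer vector \code{tri} and n x 3 matrix \code{bary}.
#' @export
locate_points <- function(mesh, pts) {
  pts <- rbind(pts)
  n <- nrow(pts)
  nx <- mesh$nx; ny <- mesh$ny
  L <- mesh$geom$length
  tri_out <- integer(n); bary_out <- matrix(NA_real_, n, 3)
  nodes <- mesh$p1$nodes; tri <- mesh$p1$tri
  ncell_tri <- nrow(tri) / 2L
  for (k in seq_len(n)) {
    x <- pts[k, 1]; y <- pts[k, 2]
    if (!is.finite(x) || !is.finite(y) || x < -1e-9 || x > L + 1e-9)
      stop("point (", x, ", ", y, ") outside the domain")
    hx <- mesh$geom$halfwidth(min(max(x, 0), L))
    eta <- (y - 5) / hx
    if (abs(eta) > 1 + 1e-6)
      stop("point (", x, ", ", y, ") outside the domain")
    i0 <- min(max(floor(x / L * nx), 0), nx - 1)
    j0 <- min(max(floor((eta + 1) / 2 * ny), 0), ny - 1)
    found <- FALSE
    for (di in c(0, -1, 1)) for (dj in c(0, -1, 1)) {
      i <- i0 + di; j <- j0 + dj
      if (i < 0 || i >= nx || j < 0 || j >= ny) next
      cell <- i * ny + j + 1
      for (t_id in c(cell, cell + ncell_tri)) {
        b <- bary_coords(nodes, tri[t_id, ], x, y)
        if (all(b > -1e-9)) {
          tri_out[k] <- t_id; bary_out[k, ] <- pmax(b, 0)
          found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) stop("failed to locate point (", x, ", ", y, ") in the mesh")
  }
  list(tri = tri_out, bary = bary_out)
}

bary_coords <- function(nodes, vids, x, y) {
  x1 <- nodes[vids[1], 1]; y1 <- nodes[vids[1], 2]
  x2 <- nodes[vids[2], 1]; y2 <- nodes[vids[2], 2]
  x3 <- nodes[vids[3], 1]; y3 <- nodes[vids[3], 2]
  d <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  l2 <- ((x - x1) * (y3 - y1) - (x3 - x1) * (y - y1)) / d
  l3 <- ((x2 - x1) * (y - y1) - (x - x1) * (y2 - y1)) / d
  c(1 - l2 - l3, l2, l3)
}

#' Interpolate a vertex field at arbitrary points
#'
#' Linear-basis interpolation of nodal values given on the vertex (linear)
#' nodes of a mesh.
#'
#' @param mesh a \code{tube_mesh}.
#' @param values numeric vector, one value per vertex node.
#' @param pts n x 2 matrix of query points.
#' @return numeric vector of interpolated values.
#' @export
interp_vertex_field <- function(mesh, values, pts) {
  stopifnot(length(values) == nrow(mesh$p1$nodes))
  loc <- locate_points(mesh, pts)
  vapply(seq_along(loc$tri), function(k) {
    sum(values[mesh$p1$tri[loc$tri[k], ]] * loc$bary[k, ])
  }, numeric(1))
}

#' Write a mesh (and optional nodal fields) as legacy-ASCII VTK
#'
#' Writes the vertex triangulation as an unstructured grid, with the
#' geometry parameters echoed in the VTK header line. Nodal scalar fields
#' (one value per vertex node) are written as POINT_DATA.
#'
#' @param mesh a \code{tube_mesh}.
#' @param path output file path.
#' @param point_data named list of numeric vectors (one value per vertex
#'   node) or two-column matrices (written as 2D vectors).
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$p1$nodes); ne <- nrow(mesh$p1$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vtk DataFile Version 3.0", con)
  writeLines(sprintf("vastra tube mesh r=%.17g L=%g W=%g nx=%d ny=%d",
                     mesh$geom$r, mesh$geom$length, mesh$geom$end_width,
                     mesh$nx, mesh$ny), con)
  writeLines(c("ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$p1$nodes[, 1], mesh$p1$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 4L * ne), con)
  writeLines(sprintf("3 %d %d %d", mesh$p1$tri[, 1] - 1L,
                     mesh$p1$tri[, 2] - 1L, mesh$p1$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("5", ne), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        stopifnot(nrow(v) == n, ncol(v) == 2)
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.17g %.17g 0", v[, 1], v[, 2]), con)
      } else {
        stopifnot(length(v) == n)
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(sprintf("%.17g", v), con)
      }
    }
  }
  invisible(path)
}

#' Read a legacy-ASCII VTK unstructured grid written by this package
#'
#' @param path file path.
#' @return list with \code{nodes} (n x 2), \code{tri} (1-based), \code{meta}
#'   (named numeric vector parsed from the header line) and \code{point_data}
#'   (named list of vectors/matrices).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  meta_tokens <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  meta <- list()
  for (tok in meta_tokens) {
    if (grepl("=", tok, fixed = TRUE)) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      meta[[kv[1]]] <- as.numeric(kv[2])
    }
  }
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(ip + 1):(ip + n)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  nodes <- pts[, 1:2, drop = FALSE]
  colnames(nodes) <- c("x", "y")
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  tri <- do.call(rbind, lapply(lines[(ic + 1):(ic + ne)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  point_data <- list()
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) {
    k <- ipd[1] + 1L
    while (k <= length(lines)) {
      hdr <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      if (length(hdr) == 0 || hdr[1] == "") { k <- k + 1L; next }
      if (hdr[1] == "SCALARS") {
        vals <- as.numeric(lines[(k + 2):(k + 1 + n)])
        point_data[[hdr[2]]] <- vals
        k <- k + 2L + n
      } else if (hdr[1] == "VECTORS") {
        m <- do.call(rbind, lapply(lines[(k + 1):(k + n)], function(s)
          as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
        point_data[[hdr[2]]] <- m[, 1:2, drop = FALSE]
        k <- k + 1L + n
      } else stop("unsupported VTK attribute: ", hdr[1])
    }
  }
  list(nodes = nodes, tri = tri, meta = meta, point_data = point_data)
}
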