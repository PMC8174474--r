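#' L2 field error between a FEM solution and the surrogate
#'
#' Both fields are represented by linear basis functions on the vertex
#' triangulation of the FEM mesh; the squared difference (a quadratic
#' polynomial per triangle) is integrated exactly, and the square root of
#' the integral is returned.
#'
#' @param fem a \code{fem_solution}.
#' @param pinn a \code{pinn}.
#' @param field one of \code{"u_x"}, \code{"u_y"}, \code{"p"}.
#' @param props \code{\link{fluid_properties}}.
#' @return the L2 norm of the field difference over the domain.
#' @export
l2_field_error <- function(fem, pinn, field = c("u_x", "u_y", "p"),
                           props = fluid_properties()) {
  field <- match.arg(field)
  d <- field_differences(fem, pinn, props)
  dv <- switch(field, u_x = d$dux, u_y = d$duy, p = d$dp)
  sqrt(l2sq_vertex_field(fem$mesh, dv))
}

# nodal differences (PINN minus FEM) at the vertex nodes
field_differences <- function(fem, pinn, props = fluid_properties()) {
  mesh <- fem$mesh
  v1 <- p2_vertex_values(mesh)
  nodes <- mesh$p1$nodes
  fl <- pinn_fields(pinn, nodes[, 1], nodes[, 2], fem$theta$f, fem$theta$r,
                    props)
  list(dux = fl$u - fem$ux[v1], duy = fl$v - fem$uy[v1], dp = fl$p - fem$p)
}

# exact integral of the square of a piecewise-linear vertex field:
# per triangle, area/6 * (sum di^2 + sum_{i<j} di dj)
l2sq_vertex_field <- function(mesh, values) {
  tri <- mesh$p1$tri
  a <- signed_area2(mesh$p1$nodes, tri) / 2
  d1 <- values[tri[, 1]]; d2 <- values[tri[, 2]]; d3 <- values[tri[, 3]]
  sum(a / 6 * (d1^2 + d2^2 + d3^2 + d1 * d2 + d1 * d3 + d2 * d3))
}

#' Mean nodal boundary velocity error of the surrogate
#'
#' Mean, over the vertex nodes of a boundary segment, of the Euclidean
#' norm of the difference between the surrogate velocity and the imposed
#' boundary data (zero on the walls, the parabolic profile on the inflow).
#'
#' @param fem a \code{fem_solution} (supplies the mesh, tags and theta).
#' @param pinn a \code{pinn}.
#' @param segment \code{"wall"} or \code{"inflow"}.
#' @return non-negative scalar in mm/s.
#' @export
boundary_nodal_error <- function(fem, pinn, segment = c("wall", "inflow")) {
  segment <- match.arg(segment)
  mesh <- fem$mesh
  sel <- mesh$p1$tag == segment
  if (!any(sel)) stop("no vertex nodes tagged ", segment)
  nodes <- mesh$p1$nodes[sel, , drop = FALSE]
  uv <- velocity_from_potential(pinn, nodes[, 1], nodes[, 2],
                                fem$theta$f, fem$theta$r)
  gx <- if (segment == "inflow") inflow_profile(fem$theta$f, nodes[, 2]) else 0
  mean(sqrt((uv[, 1] - gx)^2 + uv[, 2]^2))
}

#' Per-parameter-point evaluation report
#'
#' L2 errors of both velocity components and the pressure, and the mean
#' nodal boundary errors, for one parameter point.
#'
#' @inheritParams l2_field_error
#' @return one-row data.frame: f, r, l2_ux, l2_uy, l2_p, wall_err,
#'   inflow_err, and sq_total = l2_ux^2 + l2_uy^2 + l2_p^2 (this point's
#'   contribution to the total error E).
#' @export
evaluation_report <- function(fem, pinn, props = fluid_properties()) {
  d <- field_differences(fem, pinn, props)
  l2ux <- sqrt(l2sq_vertex_field(fem$mesh, d$dux))
  l2uy <- sqrt(l2sq_vertex_field(fem$mesh, d$duy))
  l2p <- sqrt(l2sq_vertex_field(fem$mesh, d$dp))
  data.frame(
    f = fem$theta$f, r = fem$theta$r,
    l2_ux = l2ux, l2_uy = l2uy, l2_p = l2p,
    wall_err = boundary_nodal_error(fem, pinn, "wall"),
    inflow_err = boundary_nodal_error(fem, pinn, "inflow"),
    sq_total = l2ux^2 + l2uy^2 + l2p^2
  )
}

#' Total error E over the parameter grid
#'
#' Sum over parameter points of the squared L2 errors of the two velocity
#' components and the pressure,
#' E = sum_G (int (u_x - u~_x)^2 + int (u_y - u~_y)^2 + int (p - p~)^2) dA.
#'
#' @param reports data.frame of \code{\link{evaluation_report}} rows.
#' @param grid optional \code{parameter_grid}; if given, a report must be
#'   present for every grid point.
#' @return scalar E.
#' @export
total_error_E <- function(reports, grid = NULL) {
  stopifnot(is.data.frame(reports), "sq_total" %in% names(reports))
  if (!is.null(grid)) {
    key <- function(f, r) paste(signif(f, 12), signif(r, 12))
    missing <- setdiff(key(grid$points$f, grid$points$r),
                       key(reports$f, reports$r))
    if (length(missing))
      stop("missing evaluation report for grid point(s): ",
           paste(missing, collapse = "; "))
  }
  sum(reports$sq_total)
}

#' Inverse-design pressure sweep over tube shapes
#'
#' Queries the surrogate only (no FEM solves): for each shape parameter r
#' in the range, the predicted pressure difference between the two probe
#' points at fixed inflow parameter f.
#'
#' @param pinn a \code{pinn}.
#' @param f inflow parameter.
#' @param r_range length-2 numeric; swept inclusively.
#' @param step positive sweep step.
#' @param probes list with points \code{a} and \code{b} (default
#'   (5, 5) and (95, 5) mm).
#' @param props \code{\link{fluid_properties}}.
#' @return data.frame (r, dp) with dp = p(a) - p(b) in Pa, ordered from
#'   \code{r_range[1]} to \code{r_range[2]}.
#' @export
pressure_sweep <- function(pinn, f, r_range = c(0, -2), step = 0.025,
                           probes = list(a = c(5, 5), b = c(95, 5)),
                           props = fluid_properties()) {
  stopifnot(step > 0, length(r_range) == 2)
  n <- abs(r_range[2] - r_range[1]) / step
  if (abs(n - round(n)) > 1e-9)
    stop("step does not divide the sweep range")
  rs <- seq(r_range[1], r_range[2], length.out = round(n) + 1)
  for (pt in probes) {
    hx <- vapply(rs, function(r) wall_halfwidth(pt[1], r), numeric(1))
    bad <- abs(pt[2] - 5) >= hx
    if (any(bad))
      stop("probe (", pt[1], ", ", pt[2], ") falls outside the tube for r = ",
           paste(signif(rs[bad], 4), collapse = ", "))
  }
  pa <- pinn_fields(pinn, probes$a[1], probes$a[2], f, rs, props)$p
  pb <- pinn_fields(pinn, probes$b[1], probes$b[2], f, rs, props)$p
  data.frame(r = rs, dp = pa - pb)
}

#' Find the shape parameter reaching a target pressure difference
#'
#' Sweeps the table from r = 0 towards r = -2 and returns the first r whose
#' pressure difference, rounded to 3 decimal places, reaches the rounded
#' target. A target at or below the baseline (the entry closest to r = 0)
#' returns that baseline r. The neighbouring rows around the crossing are
#' attached as the \code{"context"} attribute.
#'
#' @param sweep data.frame (r, dp) from \code{\link{pressure_sweep}}.
#' @param target target pressure difference in Pa.
#' @return the crossing r, with attribute \code{context}.
#' @export
find_r_for_target <- function(sweep, target) {
  stopifnot(is.data.frame(sweep), all(c("r", "dp") %in% names(sweep)),
            nrow(sweep) > 0, all(is.finite(sweep$dp)), is.finite(target))
  ord <- order(sweep$r, decreasing = TRUE)  # from 0 towards -2
  s <- sweep[ord, ]
  tgt <- round(target, 3)
  if (round(s$dp[1], 3) >= tgt) {
    out <- s$r[1]
    attr(out, "context") <- s[seq_len(min(2, nrow(s))), ]
    return(out)
  }
  hit <- which(round(s$dp, 3) >= tgt)
  if (!length(hit))
    stop("target dp = ", tgt, " Pa never reached; maximum attained = ",
         round(max(s$dp), 3), " Pa")
  i <- hit[1]
  out <- s$r[i]
  attr(out, "context") <- s[max(1, i - 1):min(nrow(s), i + 1), ]
  out
}
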