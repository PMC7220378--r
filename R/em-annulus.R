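#' Regular polygon approximating a circle
#'
#' Used as a convenient PSD outline: a regular \code{n}-gon inscribed so that
#' the maximum deviation from the true circle stays below \code{tol_nm}
#' (1 nm by default, matching the buffering tolerance).
#'
#' @param radius_nm Circle radius (nm).
#' @param center Numeric \code{c(x, y)} center (nm).
#' @param tol_nm Maximum sagitta (deviation from the circle) allowed.
#' @return Data frame with columns \code{x_nm}, \code{y_nm}.
#' @export
circle_polygon <- function(radius_nm, center = c(0, 0), tol_nm = 1) {
  n <- max(16L, ceiling(pi / acos(1 - tol_nm / radius_nm)))
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(x_nm = center[1] + radius_nm * cos(th),
             y_nm = center[2] + radius_nm * sin(th))
}

.check_polygon <- function(poly) {
  if (!all(c("x_nm", "y_nm") %in% names(poly)) || nrow(poly) < 3)
    stop("polygon needs >= 3 vertices with columns x_nm, y_nm", call. = FALSE)
  if (polygon_area(poly) <= 0)
    stop("degenerate polygon (zero area)", call. = FALSE)
  invisible(poly)
}

#' Polygon area by the shoelace formula
#' @param poly Data frame with columns \code{x_nm}, \code{y_nm}.
#' @return Area (nm^2), always positive.
#' @export
polygon_area <- function(poly) {
  x <- poly$x_nm; y <- poly$y_nm
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Polygon perimeter
#' @param poly Data frame with columns \code{x_nm}, \code{y_nm}.
#' @return Perimeter (nm).
#' @export
polygon_perimeter <- function(poly) {
  x <- poly$x_nm; y <- poly$y_nm
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(sqrt((x[i2] - x)^2 + (y[i2] - y)^2))
}

.is_convex <- function(poly) {
  x <- poly$x_nm; y <- poly$y_nm
  n <- length(x)
  i2 <- c(2:n, 1); i3 <- c(3:n, 1, 2)
  cr <- (x[i2] - x) * (y[i3] - y[i2]) - (y[i2] - y) * (x[i3] - x[i2])
  all(cr >= -1e-9 * max(abs(cr))) || all(cr <= 1e-9 * max(abs(cr)))
}

.in_polygon <- function(px, py, poly) {
  bnd <- cbind(c(poly$x_nm, poly$x_nm[1]), c(poly$y_nm, poly$y_nm[1]))
  mgcv::in.out(bnd, cbind(px, py))
}

# distance from points to every polygon edge segment, vectorized per segment
.min_segment_distance <- function(px, py, poly) {
  x <- poly$x_nm; y <- poly$y_nm
  n <- length(x)
  i2 <- c(2:n, 1)
  dmin <- rep(Inf, length(px))
  for (s in seq_len(n)) {
    ax <- x[s]; ay <- y[s]
    vx <- x[i2[s]] - ax; vy <- y[i2[s]] - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
          else 0
    dmin <- pmin(dmin, sqrt((px - (ax + tt * vx))^2 +
                            (py - (ay + tt * vy))^2))
  }
  dmin
}

#' Distance from points to the edge of a PSD outline
#'
#' Euclidean distance from each point to the polygon boundary for exterior
#' points; points inside (or on) the polygon get distance 0 and are flagged
#' as interior, since the perisynaptic profile measures distances outward
#' from the PSD edge.
#'
#' @param points Data frame with columns \code{x_nm}, \code{y_nm}.
#' @param psd_polygon Closed outline, data frame with \code{x_nm},
#'   \code{y_nm} (first vertex not repeated).
#' @return Data frame with columns \code{distance_nm} and \code{inside}.
#' @export
edge_distance <- function(points, psd_polygon) {
  .check_polygon(psd_polygon)
  if (nrow(points) == 0)
    return(data.frame(distance_nm = numeric(0), inside = logical(0)))
  inside <- .in_polygon(points$x_nm, points$y_nm, psd_polygon)
  d <- .min_segment_distance(points$x_nm, points$y_nm, psd_polygon)
  d[inside] <- 0
  data.frame(distance_nm = d, inside = inside)
}

#' Area of the outward round-join buffer of a polygon
#'
#' Area of the set of points within distance \code{d} of the polygon
#' (polygon interior included). For convex polygons this is exact:
#' \code{A + P d + pi d^2} (Steiner formula for round joins). For non-convex
#' polygons the boundary-distance field is integrated on a regular grid of
#' spacing \code{grid_res_nm}.
#'
#' @param poly Data frame with columns \code{x_nm}, \code{y_nm}.
#' @param d Buffer distance (nm), \code{>= 0}.
#' @param grid_res_nm Grid spacing for the non-convex fallback (nm).
#' @return Area (nm^2).
#' @export
buffer_area <- function(poly, d, grid_res_nm = 1) {
  .check_polygon(poly)
  stopifnot(d >= 0)
  if (d == 0) return(polygon_area(poly))
  if (.is_convex(poly))
    return(polygon_area(poly) + polygon_perimeter(poly) * d + pi * d^2)
  xs <- seq(min(poly$x_nm) - d, max(poly$x_nm) + d, by = grid_res_nm)
  ys <- seq(min(poly$y_nm) - d, max(poly$y_nm) + d, by = grid_res_nm)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- .in_polygon(px, py, poly)
  dd <- .min_segment_distance(px, py, poly)
  sum(inside | dd <= d) * grid_res_nm^2
}

#' Perisynaptic annulus density profile
#'
#' Bins particles by their distance from the PSD edge into half-open bands
#' \code{[b*50, (b+1)*50)} nm and divides the per-band counts by the exact
#' band areas (outward buffer rings, optionally clipped to an analysis
#' region), yielding densities in particles/um^2. Particles inside the PSD
#' and beyond the last band are counted separately so that counts are
#' conserved.
#'
#' @param sample A \code{psd_sample} (list with \code{psd_polygon} and
#'   \code{particles}) as produced by \code{\link{gen_em_sample}} or
#'   \code{\link{read_em_sample}}.
#' @param band_width Band width (nm, default 50).
#' @param n_bands Number of bands (default 5, covering [0, 250) nm).
#' @param analysis_region Optional polygon (same columns) restricting the
#'   membrane area analyzed: band areas are clipped to it (by grid
#'   integration) and particles outside it are ignored.
#' @param include_inside If \code{TRUE}, particles inside the PSD are kept in
#'   a separate "inside" row rather than only in the totals.
#' @param grid_res_nm Grid spacing used when areas cannot be computed in
#'   closed form (nm).
#' @return An object of class \code{annulus_profile}: a list with
#'   \code{bands} (data frame: band, lower_nm, upper_nm, count, area_nm2,
#'   density_per_um2), \code{inside_count}, \code{beyond_count},
#'   \code{total}.
#' @export
annulus_density_profile <- function(sample, band_width = 50, n_bands = 5,
                                    analysis_region = NULL,
                                    include_inside = FALSE,
                                    grid_res_nm = 1) {
  poly <- sample$psd_polygon
  pts <- sample$particles
  .check_polygon(poly)
  if (nrow(pts) > 0 && !is.null(analysis_region)) {
    keep <- .in_polygon(pts$x_nm, pts$y_nm, analysis_region)
    pts <- pts[keep, , drop = FALSE]
  }
  ed <- edge_distance(pts, poly)
  edges <- seq(0, by = band_width, length.out = n_bands + 1)
  band_of <- findInterval(ed$distance_nm, edges, rightmost.closed = FALSE)
  band_of[ed$inside] <- 0L

  counts <- vapply(seq_len(n_bands),
                   function(bi) sum(band_of == bi & !ed$inside), integer(1))
  inside_count <- sum(ed$inside)
  beyond_count <- sum(band_of > n_bands & !ed$inside)

  cum_area <- vapply(edges, function(dd)
    .region_buffer_area(poly, dd, analysis_region, grid_res_nm), numeric(1))
  areas <- diff(cum_area)
  dens <- ifelse(areas > 0, 1e6 * counts / areas, NA_real_)
  if (any(areas <= 0))
    warning("zero band area: density undefined for band(s) ",
            paste(which(areas <= 0), collapse = ", "))

  bands <- data.frame(band = seq_len(n_bands),
                      lower_nm = edges[-(n_bands + 1)], upper_nm = edges[-1],
                      count = counts, area_nm2 = areas,
                      density_per_um2 = dens)
  structure(list(bands = bands, inside_count = inside_count,
                 beyond_count = beyond_count,
                 total = inside_count + sum(counts) + beyond_count,
                 include_inside = include_inside),
            class = "annulus_profile")
}

# buffered area, optionally clipped to an analysis region polygon
.region_buffer_area <- function(poly, d, analysis_region, grid_res_nm) {
  if (is.null(analysis_region)) return(buffer_area(poly, d, grid_res_nm))
  pad <- d
  xs <- seq(min(poly$x_nm) - pad, max(poly$x_nm) + pad, by = grid_res_nm)
  ys <- seq(min(poly$y_nm) - pad, max(poly$y_nm) + pad, by = grid_res_nm)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- .in_polygon(px, py, poly)
  dd <- .min_segment_distance(px, py, poly)
  in_reg <- .in_polygon(px, py, analysis_region)
  sum((inside | dd <= d) & in_reg) * grid_res_nm^2
}

#' @export
print.annulus_profile <- function(x, ...) {
  cat("annulus_profile:", x$total, "particles (",
      x$inside_count, "inside PSD,", x$beyond_count, "beyond last band)\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}
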