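#' Slice geometry
#'
#' In-plane grid and through-plane thickness of one vessel-wall slice. The
#' reference grid is the T1W acquisition: 0.39 mm isotropic pixels, 3 mm
#' slices. Only isotropic in-plane grids are supported; all channels of a
#' study are assumed pre-aligned on this grid.
#'
#' @param rows,cols positive integer grid dimensions.
#' @param spacing in-plane pixel spacing in mm (isotropic).
#' @param thickness slice thickness in mm.
#' @return A `slice_geometry` object.
#' @export
slice_geometry <- function(rows = 64L, cols = 64L, spacing = 0.39,
                           thickness = 3) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("in-plane spacing must be a single positive number (mm)",
         call. = FALSE)
  }
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0) {
    stop("slice thickness must be a single positive number (mm)",
         call. = FALSE)
  }
  structure(
    list(rows = rows, cols = cols, spacing = spacing, thickness = thickness),
    class = "slice_geometry"
  )
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat(sprintf("<slice_geometry> %d x %d px, %.3g mm/px, %.3g mm thick\n",
              x$rows, x$cols, x$spacing, x$thickness))
  invisible(x)
}

#' Closed planar contour
#'
#' An ordered, closed, simple (non-self-intersecting) polygon in physical mm
#' coordinates. Roles mirror the manual delineation protocol: the lumen and
#' outer-wall contours define the annulus of classifiable wall pixels, and
#' soft-plaque contours delineate reference lesions.
#'
#' @param vertices two-column numeric matrix (x, y) in mm; the closing edge
#'   from last to first vertex is implicit.
#' @param role one of `"lumen"`, `"outer_wall"`, `"soft_plaque"`.
#' @return A `contour` object.
#' @export
contour <- function(vertices, role = c("lumen", "outer_wall", "soft_plaque")) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || !is.numeric(vertices) ||
      anyNA(vertices)) {
    stop("invalid contour: need >= 3 finite (x, y) vertices", call. = FALSE)
  }
  # drop an explicit closing vertex if present
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) {
    stop("invalid contour: need >= 3 distinct vertices", call. = FALSE)
  }
  if (abs(polygon_area(vertices)) < 1e-12) {
    stop("invalid contour: polygon has zero area", call. = FALSE)
  }
  if (!polygon_is_simple(vertices)) {
    stop("invalid contour: polygon is self-intersecting", call. = FALSE)
  }
  structure(list(vertices = vertices, role = role), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> role=%s, %d vertices, area %.3g mm^2\n",
              x$role, nrow(x$vertices), abs(polygon_area(x$vertices))))
  invisible(x)
}

#' Signed shoelace area of a polygon (mm^2)
#' @param vertices two-column matrix of vertices.
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a polygon (mm)
#' @param vertices two-column matrix of vertices.
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# non-adjacent edge pairs must not properly intersect
polygon_is_simple <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1), , drop = FALSE]
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # edge n is adjacent to edge 1
    if (length(js) == 0) next
    a <- p1[i, ]; b <- p2[i, ]
    c1 <- p1[js, 1]; c2 <- p1[js, 2]; d1 <- p2[js, 1]; d2 <- p2[js, 2]
    o1 <- orient(a[1], a[2], b[1], b[2], c1, c2)
    o2 <- orient(a[1], a[2], b[1], b[2], d1, d2)
    o3 <- orient(c1, c2, d1, d2, a[1], a[2])
    o4 <- orient(c1, c2, d1, d2, b[1], b[2])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Pixel-center coordinates of a grid
#'
#' Pixel (i, j) (1-based row i, column j) has its center at physical
#' coordinates x = (j - 0.5) * spacing, y = (i - 0.5) * spacing.
#'
#' @param geometry a [slice_geometry()].
#' @return List with vectors `x` (length cols) and `y` (length rows), mm.
#' @keywords internal
pixel_centers <- function(geometry) {
  list(
    x = (seq_len(geometry$cols) - 0.5) * geometry$spacing,
    y = (seq_len(geometry$rows) - 0.5) * geometry$spacing
  )
}

#' Rasterize a contour to a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the polygon under
#' the even-odd (crossing-number) rule; centers exactly on the boundary are
#' counted as inside.
#'
#' @param contour a [contour()].
#' @param geometry a [slice_geometry()].
#' @return rows x cols logical matrix.
#' @export
rasterize_contour <- function(contour, geometry) {
  stopifnot(inherits(contour, "contour"), inherits(geometry, "slice_geometry"))
  ctr <- pixel_centers(geometry)
  pts <- cbind(rep(ctr$x, each = geometry$rows),
               rep(ctr$y, times = geometry$cols))
  inside <- point_in_polygon(pts, contour$vertices)
  matrix(inside, nrow = geometry$rows, ncol = geometry$cols)
}

# even-odd rule, vectorized over points; boundary points inside
point_in_polygon <- function(pts, v) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(v)
  xi <- v[, 1]; yi <- v[, 2]
  xj <- c(xi[n], xi[-n]); yj <- c(yi[n], yi[-n])
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-9 * max(1, max(abs(v)))
  for (k in seq_len(n)) {
    ax <- xi[k]; ay <- yi[k]; bx <- xj[k]; by <- yj[k]
    crosses <- ((ay > py) != (by > py)) &
      (px < (bx - ax) * (py - ay) / (by - ay) + ax)
    inside <- xor(inside, crosses)
    # boundary test: |cross product| small and projection within segment
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    cr <- dx * (py - ay) - dy * (px - ax)
    dt <- dx * (px - ax) + dy * (py - ay)
    on_edge <- on_edge |
      (abs(cr) <= eps * sqrt(len2) & dt >= -eps & dt <= len2 + eps)
  }
  inside | on_edge
}

#' Vessel-wall annulus mask
#'
#' The classifiable wall region: pixels inside the outer-wall contour but not
#' inside the lumen contour.
#'
#' @param lumen,outer [contour()] objects for the lumen and outer wall.
#' @param geometry a [slice_geometry()].
#' @return rows x cols logical matrix.
#' @export
wall_mask <- function(lumen, outer, geometry) {
  m <- rasterize_contour(outer, geometry) & !rasterize_contour(lumen, geometry)
  if (!any(m)) {
    stop("empty vessel wall: lumen and outer contours leave no annulus pixels",
         call. = FALSE)
  }
  m
}

#' Regular-polygon approximation of a circle
#'
#' @param center length-2 numeric (x, y) in mm.
#' @param radius radius in mm.
#' @param n number of vertices.
#' @param role contour role.
#' @return A [contour()].
#' @export
circle_contour <- function(center, radius, n = 96L,
                           role = c("lumen", "outer_wall", "soft_plaque")) {
  role <- match.arg(role)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)),
          role = role)
}
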