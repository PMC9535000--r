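# Triangulated irregular network (TIN) interpolation.
#
# A Delaunay triangulation is built over the sample coordinates
# (Bowyer-Watson incremental insertion; coordinates are treated as planar,
# which is accurate over a ~130 km^2 extent) and values are interpolated
# piecewise-linearly with barycentric weights inside each triangle.
# Queries outside the convex hull return NA (no-data), as in GIS TIN
# rasters.

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.eps) return(NULL)  # degenerate triangle
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # centre and squared radius
}

#' Delaunay triangulation of planar points
#'
#' Bowyer-Watson incremental algorithm.  Suitable for the modest point
#' counts of a sampling campaign (tens to a few hundred sites).
#'
#' @param pts two-column numeric matrix (x, y); at least 3 non-collinear
#'   rows, no duplicates.
#' @return integer matrix, one triangle per row (indices into \code{pts}).
#' @export
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  assert_that(ncol(pts) == 2 && nrow(pts) >= 3,
              "need at least 3 planar points")
  assert_that(!anyNA(pts) && all(is.finite(pts)), "non-finite coordinates")
  if (anyDuplicated(round(pts, 12)))
    stop_pelnet("duplicate points in triangulation input")
  ctr <- scale(pts, scale = FALSE)
  if (svd(ctr)$d[2] < 1e-10 * max(svd(ctr)$d[1], 1))
    stop_pelnet("points are collinear; triangulation undefined")
  n <- nrow(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  big <- 20 * span
  super <- rbind(c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  all_pts <- rbind(pts, super)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  circ <- list(circumcircle(super[1, ], super[2, ], super[3, ]))
  for (ip in seq_len(n)) {
    p <- all_pts[ip, ]
    bad <- vapply(circ, function(cc) {
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, TRUE)
    cavity <- tris[bad, , drop = FALSE]
    edges <- rbind(cavity[, c(1, 2)], cavity[, c(2, 3)], cavity[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    circ <- circ[!bad]
    for (e in seq_len(nrow(boundary))) {
      newt <- c(boundary[e, ], ip)
      tris <- rbind(tris, newt)
      circ <- c(circ, list(circumcircle(all_pts[newt[1], ],
                                        all_pts[newt[2], ],
                                        all_pts[newt[3], ])))
    }
  }
  keep <- apply(tris <= n, 1, all)
  out <- tris[keep, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

barycentric_weights <- function(pts, tri, qx, qy) {
  a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
  d <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (qx - c[1]) + (c[1] - b[1]) * (qy - c[2])) / d
  l2 <- ((c[2] - a[2]) * (qx - c[1]) + (a[1] - c[1]) * (qy - c[2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

#' TIN interpolation of point values over a regular grid
#'
#' @param points data.frame with columns \code{lon}, \code{lat} and a value
#'   column (default \code{shannon}).
#' @param value name of the value column.
#' @param grid_res number of grid nodes per axis (default 100).
#' @return a \code{tin_surface}: the triangulation plus a long-format grid
#'   data.frame (lon, lat, value, nodata flag).
#' @export
tin_interpolate <- function(points, value = "shannon", grid_res = 100) {
  assert_that(all(c("lon", "lat", value) %in% names(points)),
              "points need lon, lat and '", value, "' columns")
  pts <- as.matrix(points[, c("lon", "lat")])
  vals <- points[[value]]
  tris <- delaunay_triangulate(pts)
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = grid_res)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = grid_res)
  grid <- expand.grid(lon = gx, lat = gy)
  gv <- tin_eval(pts, vals, tris, grid$lon, grid$lat)
  grid$value <- gv
  grid$nodata <- is.na(gv)
  structure(list(points = pts, values = vals, triangles = tris, grid = grid),
            class = "tin_surface")
}

tin_eval <- function(pts, vals, tris, qx, qy) {
  out <- rep(NA_real_, length(qx))
  tol <- -1e-9
  for (t in seq_len(nrow(tris))) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    w <- barycentric_weights(pts, tris[t, ], qx[todo], qy[todo])
    inside <- w[, 1] >= tol & w[, 2] >= tol & w[, 3] >= tol
    if (any(inside)) {
      idx <- todo[inside]
      out[idx] <- w[inside, , drop = FALSE] %*% vals[tris[t, ]]
    }
  }
  # exact vertex identity: snap queries that coincide with a data point
  for (i in seq_len(nrow(pts))) {
    hit <- qx == pts[i, 1] & qy == pts[i, 2]
    if (any(hit)) out[hit] <- vals[i]
  }
  out
}

#' Evaluate a TIN surface at arbitrary coordinates
#'
#' @param surface a \code{tin_surface}.
#' @param lon,lat query coordinates.
#' @return interpolated values; NA outside the convex hull.
#' @export
tin_query <- function(surface, lon, lat) {
  tin_eval(surface$points, surface$values, surface$triangles, lon, lat)
}

#' @export
print.tin_surface <- function(x, ...) {
  cat(sprintf("tin_surface: %d vertices, %d triangles, %d grid nodes (%d no-data)\n",
              nrow(x$points), nrow(x$triangles), nrow(x$grid),
              sum(x$grid$nodata)))
  invisible(x)
}
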