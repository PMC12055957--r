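#' Contour profile of a projected cell shape
#'
#' Builds the closed x-z contour used by the deformability-cytometry shape
#' metrics: the 2D convex hull of a point set (micrometres), with its area,
#' perimeter, centroid and axis-aligned extents.
#'
#' @param points n x 2 matrix of (x, z) coordinates (um).
#' @return object of class `contour_profile`: list with `points` (closed
#'   hull polygon, one row per vertex, not repeated), `area` (um^2),
#'   `perimeter` (um), `centroid`, `extent_x`, `extent_z`.
#' @export
contour_profile <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  pts <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(pts) < 3) stop("need at least 3 distinct projected points")
  h <- grDevices::chull(pts)
  P <- pts[h, , drop = FALSE]   # counter-clockwise hull
  n <- nrow(P)
  nxt <- c(2:n, 1)
  area <- 0.5 * abs(sum(P[, 1] * P[nxt, 2] - P[nxt, 1] * P[, 2]))
  per <- sum(sqrt(rowSums((P[nxt, ] - P)^2)))
  structure(list(points = P, area = area, perimeter = per,
                 centroid = colMeans(P),
                 extent_x = diff(range(P[, 1])),
                 extent_z = diff(range(P[, 2]))),
            class = "contour_profile")
}

#' Project a membrane mesh onto the x-z plane
#'
#' Convex hull of the vertex (x, z) coordinates, the standard
#' projection for the deformation index.  Mesh coordinates in metres are
#' converted to micrometres.
#'
#' @param mesh a [tri_mesh()].
#' @return a [contour_profile()] in um.
#' @export
project_xz <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  contour_profile(mesh$vertices[, c(1, 3)] * 1e6)
}

#' Deformation index
#'
#' Non-circularity of a projected contour,
#' \deqn{DI = 1 - 2\sqrt{\pi A} / P,}
#' with `A` and `P` the area and perimeter of the convex-hull contour.
#' Zero for a circle, approaching 1 for extreme elongation.
#'
#' @param contour a [contour_profile()].
#' @return DI (dimensionless).
#' @export
deformation_index <- function(contour) {
  stopifnot(inherits(contour, "contour_profile"))
  if (contour$perimeter <= 0) stop("contour has zero perimeter")
  1 - 2 * sqrt(pi * contour$area) / contour$perimeter
}

#' Taylor deformation parameter
#'
#' \deqn{D_{XZ} = (a_3 - a_1)/(a_3 + a_1)} from the maximum dimensions of
#' the x-z contour: `a_1` along the x axis and `a_3` along the z axis.  In
#' the cross-slot this is positive when the cell is elongated along the
#' outgoing (z) axis; the sign flips under a 90 degree in-plane rotation.
#'
#' @param contour a [contour_profile()].
#' @return D_XZ in (-1, 1).
#' @export
taylor_parameter <- function(contour) {
  stopifnot(inherits(contour, "contour_profile"))
  a1 <- contour$extent_x
  a3 <- contour$extent_z
  if (a3 + a1 <= 0) stop("degenerate contour extents")
  (a3 - a1) / (a3 + a1)
}

#' Resample a closed contour to equal arc-length spacing
#'
#' @param points n x 2 closed polygon (vertices not repeated).
#' @param n number of output points.
#' @return n x 2 matrix.
#' @export
resample_contour <- function(points, n = 512) {
  P <- as.matrix(points)
  P <- rbind(P, P[1, ])
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  stot <- s[length(s)]
  if (stot <= 0) stop("contour has zero length")
  so <- seq(0, stot, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, P[, 1], xout = so)$y,
        stats::approx(s, P[, 2], xout = so)$y)
}

#' Directed mean Hausdorff distance between contours
#'
#' \deqn{\bar h(R, S) = \frac{1}{m} \sum_{r \in R} \min_{s \in S} d(r, s),}
#' the average distance from each point of `R` (the simulated contour) to
#' its nearest point of `S` (the observed contour).  Both contours are first
#' translated so their centroids coincide, and both are resampled to equal
#' arc-length spacing.  Note the measure is directed:
#' `mean_hausdorff(R, S)` and `mean_hausdorff(S, R)` differ in general.
#'
#' @param R,S contours: a [contour_profile()], or an n x 2 matrix of points
#'   (um).
#' @param n_resample number of resampled points per contour (`0` disables
#'   resampling and uses the raw points).
#' @param align subtract centroids before measuring (default TRUE).
#' @return mean nearest-point distance (um).
#' @export
mean_hausdorff <- function(R, S, n_resample = 512, align = TRUE) {
  getpts <- function(x) {
    if (inherits(x, "contour_profile")) x$points else as.matrix(x)
  }
  Rp <- getpts(R)
  Sp <- getpts(S)
  if (!nrow(Rp) || !nrow(Sp)) stop("empty point set")
  if (n_resample > 0 && nrow(Rp) >= 3) Rp <- resample_contour(Rp, n_resample)
  if (n_resample > 0 && nrow(Sp) >= 3) Sp <- resample_contour(Sp, n_resample)
  if (align) {
    Rp <- sweep(Rp, 2, colMeans(Rp))
    Sp <- sweep(Sp, 2, colMeans(Sp))
  }
  d2 <- outer(rowSums(Rp^2), rowSums(Sp^2), "+") - 2 * Rp %*% t(Sp)
  mean(sqrt(pmax(d2, 0)[cbind(seq_len(nrow(Rp)), max.col(-d2))]))
}
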