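#' Channel geometry objects
#'
#' A `channel_geometry` bundles the lattice flag field, Bouzidi wall-link
#' fractions, pressure-plane bookkeeping and the signed-distance-like
#' function `sdf` (positive in fluid) for one of the two computational
#' domains: the constricted channel (45 degree converging section followed
#' by a narrow straight square channel, junction corners rounded) or the
#' cross-slot (four square branches meeting at a junction with rounded
#' reentrant corners; inlets along x, outlets along z).
#'
#' Coordinates: `x` is the flow axis, `y` the channel height, `z` the
#' lateral axis.  The origin sits at the straight-channel entry
#' (constricted) or the cross centre (cross-slot).  Lattice nodes are
#' cell-centred: node (i, j, k) is at `origin_corner + (c(i,j,k) - 0.5) dx`.
#'
#' @name channel_geometry
NULL

node_coords <- function(geom) {
  list(x = geom$corner[1] + (seq_len(geom$dims[1]) - 0.5) * geom$dx,
       y = geom$corner[2] + (seq_len(geom$dims[2]) - 0.5) * geom$dx,
       z = geom$corner[3] + (seq_len(geom$dims[3]) - 0.5) * geom$dx)
}

finish_geometry <- function(kind, dims, dx, corner, sdf, plane_axes, params) {
  co <- list(x = corner[1] + (seq_len(dims[1]) - 0.5) * dx,
             y = corner[2] + (seq_len(dims[2]) - 0.5) * dx,
             z = corner[3] + (seq_len(dims[3]) - 0.5) * dx)
  G <- expand.grid(x = co$x, y = co$y, z = co$z, KEEP.OUT.ATTRS = FALSE)
  phi <- sdf(as.matrix(G))
  flags <- array(ifelse(phi > 0, 1L, 0L), dims)
  # pressure planes on the requested box faces (only fluid nodes)
  planes <- data.frame(axis = integer(), side = integer(), rho = numeric())
  p <- 0
  for (pa in plane_axes) {
    p <- p + 1
    ax <- pa$axis
    sl <- if (pa$side == 0) 1 else dims[ax]
    idx <- switch(ax,
                  flags[sl, , ] == 1L,
                  flags[, sl, ] == 1L,
                  flags[, , sl] == 1L)
    if (ax == 1) flags[sl, , ][idx] <- 1L + p
    if (ax == 2) flags[, sl, ][idx] <- 1L + p
    if (ax == 3) flags[, , sl][idx] <- 1L + p
    planes <- rbind(planes,
                    data.frame(axis = ax, side = pa$side, rho = 1,
                               role = pa$role))
  }
  geom <- structure(list(kind = kind, dims = dims, dx = dx, corner = corner,
                         flags = flags, planes = planes, sdf = sdf,
                         params = params, qlink = NULL),
                    class = "channel_geometry")
  geom$qlink <- boundary_links(geom)
  geom
}

#' Constricted microchannel domain
#'
#' Square-cross-section straight channel of width `l` preceded by a 45
#' degree converging section; the two junction corners are rounded with
#' circular arcs of radius `corner_r` tangent to both wall lines.  A short
#' straight inlet segment of the full inlet width precedes the converging
#' section.  The inlet (x min) and outlet (x max) faces carry pressure
#' planes.
#'
#' @param l narrow-channel width (m).
#' @param corner_r corner fillet radius (m).
#' @param straight_len narrow straight channel length (m).
#' @param height channel height (m); equal to `l` for the square duct.
#' @param converging_len length of the 45 degree converging section (m); the
#'   inlet width is `l + 2 converging_len`.
#' @param inlet_len extra straight inlet segment length (m).
#' @param nodes_per_l lattice resolution: nodes across the narrow width.
#' @return a `channel_geometry`.
#' @export
build_constricted <- function(l = 20e-6, corner_r = 20e-6,
                              straight_len = 400e-6, height = 20e-6,
                              converging_len = 120e-6, inlet_len = 20e-6,
                              nodes_per_l = 64) {
  dx <- l / nodes_per_l
  Win <- l + 2 * converging_len
  if (corner_r < 0 || corner_r * (sqrt(2) - 1) > straight_len)
    stop("corner radius incompatible with the channel dimensions")
  xmin <- -(converging_len + inlet_len)
  dims <- c(round((straight_len - xmin) / dx),
            round(height / dx),
            round(Win / dx))
  corner <- c(xmin, -height / 2, -Win / 2)
  xc <- corner_r * (sqrt(2) - 1)   # fillet centre x; centre z = l/2 + corner_r
  sdf <- function(P) {
    x <- P[, 1]; y <- P[, 2]; z <- abs(P[, 3])
    w <- l / 2 + pmin(pmax(-x, 0), converging_len)
    phi <- pmin(w - z, height / 2 - abs(P[, 2]))
    dc <- sqrt((x - xc)^2 + (z - (l / 2 + corner_r))^2) - corner_r
    pmin(phi, dc)
  }
  finish_geometry("constricted", dims, dx, corner, sdf,
                  list(list(axis = 1, side = 0, role = "inlet"),
                       list(axis = 1, side = 1, role = "outlet")),
                  list(l = l, corner_r = corner_r,
                       straight_len = straight_len, height = height,
                       converging_len = converging_len,
                       inlet_len = inlet_len, nodes_per_l = nodes_per_l))
}

#' Cross-slot microchannel domain
#'
#' Four square-section branches of width `l` meeting at a cross junction;
#' the four reentrant corners are rounded with arcs of radius `corner_r`.
#' The cell-feeding branch extends along -x for `feed_len` beyond the
#' junction square; the opposing inlet branch and the two outlet branches
#' (along z) have length `other_len`.  Pressure planes: inlets on both x
#' faces, outlets on both z faces.
#'
#' @param l branch width (m).
#' @param corner_r reentrant corner radius (m).
#' @param feed_len feeding branch length beyond the junction (m).
#' @param other_len length of the other three branches (m).
#' @param height channel height (m).
#' @param nodes_per_l lattice resolution across a branch.
#' @return a `channel_geometry`.
#' @export
build_cross_slot <- function(l = 40e-6, corner_r = 10e-6, feed_len = 440e-6,
                             other_len = 160e-6, height = 40e-6,
                             nodes_per_l = 64) {
  dx <- l / nodes_per_l
  dims <- c(round((feed_len + l + other_len) / dx),
            round(height / dx),
            round((l + 2 * other_len) / dx))
  corner <- c(-(feed_len + l / 2), -height / 2, -(other_len + l / 2))
  cc <- l / 2 + corner_r
  sdf <- function(P) {
    x <- abs(P[, 1]); z <- abs(P[, 3])
    phi_x <- l / 2 - z            # x-branch strip
    phi_z <- l / 2 - x            # z-branch strip
    # rounded reentrant corner: the pocket between the sharp corner point
    # and the arc of radius corner_r about (l/2 + r, l/2 + r) is fluid
    phi_c <- pmin(sqrt((x - cc)^2 + (z - cc)^2) - corner_r,
                  cc - x, cc - z)
    phi <- pmax(phi_x, phi_z, phi_c)
    pmin(phi, height / 2 - abs(P[, 2]))
  }
  finish_geometry("cross_slot", dims, dx, corner, sdf,
                  list(list(axis = 1, side = 0, role = "inlet"),
                       list(axis = 1, side = 1, role = "inlet"),
                       list(axis = 3, side = 0, role = "outlet"),
                       list(axis = 3, side = 1, role = "outlet")),
                  list(l = l, corner_r = corner_r, feed_len = feed_len,
                       other_len = other_len, height = height,
                       nodes_per_l = nodes_per_l))
}

#' Bouzidi wall-link fractions
#'
#' For every lattice link from a fluid node into a wall node, computes the
#' fraction `q` of the link lying in fluid by bisection on the geometry's
#' signed-distance function.
#'
#' @param geom a `channel_geometry`.
#' @return array (19 x nx x ny x nz), `-1` where no wall link.
#' @export
boundary_links <- function(geom) {
  cx <- c(0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0)
  cy <- c(0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1)
  cz <- c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1)
  dims <- geom$dims
  fl <- geom$flags != 0L
  co <- node_coords(geom)
  ql <- array(-1, c(19, dims))
  fluid_idx <- which(fl, arr.ind = TRUE)
  for (i in 2:19) {
    ni <- fluid_idx
    ni[, 1] <- ni[, 1] + cx[i]
    ni[, 2] <- ni[, 2] + cy[i]
    ni[, 3] <- ni[, 3] + cz[i]
    inb <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
      ni[, 2] >= 1 & ni[, 2] <= dims[2] &
      ni[, 3] >= 1 & ni[, 3] <= dims[3]
    solid <- rep(TRUE, nrow(ni))
    solid[inb] <- !fl[ni[inb, , drop = FALSE]]
    sel <- which(solid)
    if (!length(sel)) next
    P0 <- cbind(co$x[fluid_idx[sel, 1]], co$y[fluid_idx[sel, 2]],
                co$z[fluid_idx[sel, 3]])
    D <- cbind(rep(cx[i], length(sel)), cy[i], cz[i]) * geom$dx
    lo <- rep(0, length(sel))
    hi <- rep(1, length(sel))
    for (it in 1:40) {
      mid <- 0.5 * (lo + hi)
      inside <- geom$sdf(P0 + mid * D) > 0
      lo[inside] <- mid[inside]
      hi[!inside] <- mid[!inside]
    }
    q <- 0.5 * (lo + hi)
    ind <- cbind(i, fluid_idx[sel, , drop = FALSE])
    ql[ind] <- q
  }
  ql
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry (%s): %d x %d x %d nodes, dx = %.3g um\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3], x$dx * 1e6))
  cat(sprintf("  fluid nodes: %d, pressure planes: %d\n",
              sum(x$flags >= 1), nrow(x$planes)))
  invisible(x)
}

#' Physical position of lattice nodes
#'
#' @param geom a `channel_geometry`.
#' @return list of coordinate vectors `x`, `y`, `z` (m) for the node centres.
#' @export
lattice_coordinates <- function(geom) node_coords(geom)
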