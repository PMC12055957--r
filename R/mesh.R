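#' Triangulated surface mesh
#'
#' Constructor for a closed triangulated membrane mesh carrying both the
#' current vertex positions and the stress-free reference configuration.
#'
#' @param vertices n x 3 matrix of vertex positions (m).
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   consistent outward winding.
#' @param reference_vertices stress-free positions; defaults to `vertices`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, reference_vertices = vertices) {
  vertices <- as.matrix(vertices)
  reference_vertices <- as.matrix(reference_vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(reference_vertices) == 3,
            nrow(reference_vertices) == nrow(vertices),
            min(triangles) >= 1, max(triangles) <= nrow(vertices))
  m <- structure(list(vertices = vertices, triangles = triangles,
                      reference_vertices = reference_vertices),
                 class = "tri_mesh")
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Spherical mesh by recursive octahedron subdivision
#'
#' Starts from a regular octahedron and applies `subdivisions` rounds of
#' 1-to-4 triangle splitting, projecting every vertex onto the sphere.  The
#' counts are F = 8 * 4^n faces and V = F/2 + 2 vertices, so n = 5 gives the
#' production mesh of 8192 elements and 4098 nodes.
#'
#' @param subdivisions number of refinement rounds (>= 0).
#' @param radius sphere radius (m).
#' @param center length-3 centre position (m).
#' @return A [tri_mesh()] with outward-oriented faces.
#' @export
make_sphere_mesh <- function(subdivisions = 5, radius = 1,
                             center = c(0, 0, 0)) {
  if (length(subdivisions) != 1 || subdivisions < 0 ||
      subdivisions != round(subdivisions))
    stop("'subdivisions' must be a non-negative integer")
  stopifnot(radius > 0, length(center) == 3)
  V <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  # outward-wound octahedron faces
  Tr <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
              c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdivisions)) {
    edges <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(key)
    mid_id <- match(key, ukey) + nrow(V)
    ue <- edges[!duplicated(key), , drop = FALSE]
    mid <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    V <- rbind(V, mid)
    nf <- nrow(Tr)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    Tr <- rbind(cbind(Tr[, 1], m12, m31),
                cbind(m12, Tr[, 2], m23),
                cbind(m31, m23, Tr[, 3]),
                cbind(m12, m23, m31))
  }
  V <- sweep(V * radius, 2, center, "+")
  tri_mesh(V, Tr)
}

#' Mesh quality and geometry measures
#'
#' Total surface area, enclosed volume (signed by the divergence theorem,
#' positive for outward-wound faces), and the per-vertex mean curvature from
#' the cotangent Laplace-Beltrami operator with barycentric vertex areas
#' (positive for a sphere with outward normals).
#'
#' @param mesh a [tri_mesh()].
#' @return list with `area`, `volume`, `vertex_H`, `vertex_area`,
#'   `vertex_normal`.
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_closed(mesh)
  r <- cpp_mesh_measures(mesh$vertices, mesh$triangles)
  list(area = r$area, volume = r$volume, vertex_H = r$vertex_H,
       vertex_area = r$vertex_area, vertex_normal = r$vertex_normal)
}

check_closed <- function(mesh) {
  e <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
             mesh$triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2))
    stop("mesh is not closed: every edge must be shared by exactly 2 triangles")
  invisible(TRUE)
}

#' Euler characteristic of a mesh
#' @param mesh a [tri_mesh()].
#' @return integer V - E + F (2 for genus-0 closed surfaces).
#' @export
euler_characteristic <- function(mesh) {
  e <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
             mesh$triangles[, c(3, 1)])
  ne <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - ne + nrow(mesh$triangles)
}

#' Per-element membrane kinematics
#'
#' Computes, for every flat triangular element, the principal in-plane
#' stretches and directions of the affine map from the reference triangle,
#' the strain invariants `I1 = lambda1^2 + lambda2^2 - 2` and
#' `I2 = (lambda1 lambda2)^2 - 1`, and (when a previous configuration is
#' given) the in-plane strain-rate tensor `D` obtained from the nodal
#' velocities `(x - x_prev)/dt` with linear shape functions on the current
#' element.
#'
#' @param mesh a [tri_mesh()] (current + reference configurations).
#' @param previous_vertices optional n x 3 positions at the previous step.
#' @param dt time step (s) separating the two configurations.
#' @return list of per-element vectors: `lambda1 >= lambda2`, unit principal
#'   directions `e1`, `e2` (rows), `I1`, `I2`, and with `previous_vertices`
#'   also `D11`, `D22`, `D12` (in-plane components on the (e1-like) local
#'   frame) and `trD`, the rate of relative area change.
#' @export
element_kinematics <- function(mesh, previous_vertices = NULL, dt = 1) {
  stopifnot(inherits(mesh, "tri_mesh"), dt > 0)
  if (!is.null(previous_vertices)) {
    previous_vertices <- as.matrix(previous_vertices)
    stopifnot(all(dim(previous_vertices) == dim(mesh$vertices)))
  }
  cpp_element_kinematics(mesh$vertices, mesh$reference_vertices,
                         mesh$triangles, previous_vertices, dt)
}
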