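#' Read a contour series from CSV
#'
#' Expected header: `frame, s, point_index, x_um, z_um`, where `s` is the
#' frame's abscissa (time in seconds or axial position; constant within a
#' frame).  Frames must appear with strictly increasing `s`.
#'
#' @param path CSV file.
#' @return list of class `contour_series`: `frames` (list of n x 2 matrices,
#'   um) and `s` (per-frame abscissa).
#' @export
read_contours <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "s", "point_index", "x_um", "z_um")
  if (!all(need %in% names(d)))
    stop("contour CSV must have header: ", paste(need, collapse = ", "))
  for (col in c("s", "x_um", "z_um")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1])
    if (anyNA(v)) stop("missing value in column '", col, "'")
    d[[col]] <- v
  }
  fr <- split(d, d$frame)
  fr <- fr[order(as.numeric(names(fr)))]
  s <- vapply(fr, function(x) x$s[1], numeric(1))
  if (length(s) > 1 && any(diff(s) <= 0))
    stop("frame abscissae must be strictly increasing")
  frames <- lapply(fr, function(x) {
    x <- x[order(x$point_index), ]
    cbind(x_um = x$x_um, z_um = x$z_um)
  })
  structure(list(frames = frames, s = unname(s)), class = "contour_series")
}

#' Write a contour series to CSV
#'
#' @param series a `contour_series` (or list with `frames`, `s`).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_contours <- function(series, path) {
  stopifnot(!is.null(series$frames), length(series$frames) == length(series$s))
  rows <- lapply(seq_along(series$frames), function(i) {
    P <- series$frames[[i]]
    data.frame(frame = i, s = series$s[i],
               point_index = seq_len(nrow(P)),
               x_um = P[, 1], z_um = P[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Synthetic pseudo-experiment from a forward simulation
#'
#' Stand-in for an experimental recording: runs a reduced-resolution forward
#' transit at known parameters, extracts the contour and shape-metric
#' series, and optionally perturbs the contour points with seeded Gaussian
#' noise.  Regenerating with the same seed is bit-identical; the forward
#' simulation itself is deterministic.
#'
#' @param config a [transit_config()] holding the true parameters.
#' @param noise_sigma contour noise standard deviation (um).
#' @param seed RNG seed for the noise.
#' @param calibration optional pre-computed [calibrate_pressure()] result.
#' @return list of class `pseudo_experiment`: `series` (the trajectory data
#'   frame), `contours` (noisy), `contours_clean`, `truth` (named
#'   parameters), `noise_sigma`, `seed`.
#' @export
make_pseudo_experiment <- function(config, noise_sigma = 0, seed = 1,
                                   calibration = NULL) {
  tr <- run_transit(config, calibration = calibration)
  pseudo_experiment_from_record(tr, noise_sigma = noise_sigma, seed = seed)
}

#' Pseudo-experiment from an existing transit record
#'
#' Applies the seeded contour-noise layer of [make_pseudo_experiment()] to a
#' transit that has already been simulated.
#'
#' @param record a `capsule_transit`.
#' @param noise_sigma contour noise standard deviation (um).
#' @param seed RNG seed.
#' @return a `pseudo_experiment`.
#' @export
pseudo_experiment_from_record <- function(record, noise_sigma = 0, seed = 1) {
  stopifnot(inherits(record, "capsule_transit"))
  config <- record$config
  contours <- record$contours
  if (noise_sigma > 0) {
    set.seed(seed)
    contours <- lapply(contours, function(P)
      P + matrix(stats::rnorm(length(P), 0, noise_sigma), nrow(P), 2))
  }
  structure(list(series = record$series, contours = contours,
                 contours_clean = record$contours,
                 truth = c(Ca = config$groups$Ca, C = config$groups$C,
                           eta = config$groups$eta, d_oc = config$d_oc_z),
                 noise_sigma = noise_sigma, seed = seed,
                 events = record$events, record = record),
            class = "pseudo_experiment")
}

#' Closed-form flow fixtures
#'
#' Reference solutions used as oracles for the flow solver: plane Poiseuille
#' flow of a Newtonian or power-law liquid between parallel plates, the
#' Fourier-series solution of the square duct, and a linear shear field.
#'
#' @param case one of `"plane_poiseuille_newtonian"`,
#'   `"plane_poiseuille_powerlaw"`, `"square_duct_newtonian"`,
#'   `"linear_shear"`.
#' @param params named list: `G` pressure gradient (Pa/m), `mu` viscosity
#'   (Pa s) or `K`/`alpha` for the power law, `h` half-gap (m), `b`
#'   half-width (m), `gamma` shear rate (1/s), `nterms` series length.
#' @param coords coordinates at which to evaluate: vector `z` (and `y` for
#'   the duct, same length or a grid via `expand = TRUE`).
#' @param expand if `TRUE`, evaluate the duct solution on the y x z grid.
#' @return list with `u` (m/s) and where defined `gamma_dot` (1/s); for the
#'   duct also `Q_coef`: the flow-rate coefficient
#'   `Q mu / (G (2b)^4)` of the series solution.
#' @export
analytic_flow_fixtures <- function(case, params, coords = NULL,
                                   expand = FALSE) {
  case <- match.arg(case, c("plane_poiseuille_newtonian",
                            "plane_poiseuille_powerlaw",
                            "square_duct_newtonian", "linear_shear"))
  p <- params
  if (case == "plane_poiseuille_newtonian") {
    z <- coords$z
    u <- p$G / (2 * p$mu) * (p$h^2 - z^2)
    list(u = u, gamma_dot = abs(p$G * z / p$mu))
  } else if (case == "plane_poiseuille_powerlaw") {
    z <- coords$z
    n <- 1 / p$alpha
    Ks <- p$K * p$gamma0^(1 - p$alpha)
    u <- (p$G / Ks)^n * (p$h^(n + 1) - abs(z)^(n + 1)) / (n + 1)
    list(u = u, gamma_dot = (p$G * abs(z) / Ks)^n)
  } else if (case == "square_duct_newtonian") {
    b <- p$b
    nt <- if (is.null(p$nterms)) 200 else p$nterms
    k <- seq(1, 2 * nt - 1, by = 2)
    # u(y,z) over the square [-b,b]^2, series in cosh/cos
    ufun <- function(y, z) {
      s <- 0
      for (i in k) {
        bet <- i * pi / (2 * b)
        s <- s + (-1)^((i - 1) / 2) / i^3 *
          (1 - cosh(bet * y) / cosh(bet * b)) * cos(bet * z)
      }
      (16 * p$G * b^2 / (p$mu * pi^3)) * s
    }
    out <- list()
    if (!is.null(coords)) {
      if (expand) {
        out$u <- outer(coords$y, coords$z, Vectorize(ufun))
      } else {
        out$u <- mapply(ufun, coords$y, coords$z)
      }
    }
    bracket <- 1 - (192 / pi^5) * sum(tanh(k * pi / 2) / k^5)
    out$Q <- (4 * p$G * b^4 / (3 * p$mu)) * bracket
    out$Q_coef <- out$Q * p$mu / (p$G * (2 * b)^4)
    out
  } else {
    z <- coords$z
    list(u = p$gamma * z, gamma_dot = rep(abs(p$gamma), length(z)))
  }
}

#' Export a triangulated mesh to legacy VTK polydata
#'
#' @param mesh a [tri_mesh()].
#' @param path output `.vtk` file.
#' @param point_data optional named list of per-vertex scalars or 3-column
#'   matrices.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  Tr <- mesh$triangles - 1L
  writeLines(c("# vtk DataFile Version 3.0", "capsuleflow mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V))), con)
  utils::write.table(V, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(Tr), 4 * nrow(Tr)), con)
  utils::write.table(cbind(3L, Tr), con, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(V)), con)
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(d, con, row.names = FALSE, col.names = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(d, scientific = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Export lattice fields to legacy VTK structured points
#'
#' @param fields named list of arrays (nx x ny x nz).
#' @param dx lattice spacing (m).
#' @param path output `.vtk` file.
#' @param origin physical position of the first node (m).
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(fields, dx, path, origin = c(0, 0, 0)) {
  d <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "capsuleflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", dx, dx, dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(aperm(fields[[nm]], c(1, 2, 3))),
                      scientific = TRUE), con)
  }
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Sections: `geometry` (kind plus dimensions in um), `fluid` (SI units),
#' `cell` (dimensionless groups), `run` (release, offsets, resolution,
#' numerics).  Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "fluid", "cell", "run", "fitting", "output")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  key_sets <- list(
    geometry = c("kind", "l_um", "corner_r_um", "straight_len_um",
                 "converging_len_um", "inlet_len_um", "feed_len_um",
                 "other_len_um", "height_um", "nodes_per_l"),
    fluid = c("K", "alpha", "gamma0", "gamma_min", "gamma_max", "rho",
              "mu0"),
    cell = c("Ca", "C", "eta", "lambda", "confinement", "an_over_a"),
    run = c("U", "d_oc_z", "d_oc_y", "release_x_um", "mesh_subdiv",
            "mesh_subdiv_nucleus", "dt_safety", "record_every",
            "max_tstar"),
    fitting = c("tol_DI", "Ca_grid", "C_grid", "eta_grid", "d_grid"),
    output = c("dir", "vtk", "contours"))
  for (sec in intersect(names(cfg), names(key_sets))) {
    extra <- setdiff(names(cfg[[sec]]), key_sets[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Build a transit configuration from a run configuration
#'
#' @param cfg a `run_config` from [read_run_config()].
#' @return a [transit_config()].
#' @export
transit_config_from_run_config <- function(cfg) {
  gy <- cfg$geometry
  um <- 1e-6
  geom <- if (identical(gy$kind, "cross_slot")) {
    build_cross_slot(l = gy$l_um * um, corner_r = gy$corner_r_um * um,
                     feed_len = gy$feed_len_um * um,
                     other_len = gy$other_len_um * um,
                     height = gy$height_um * um,
                     nodes_per_l = gy$nodes_per_l)
  } else {
    build_constricted(l = gy$l_um * um, corner_r = gy$corner_r_um * um,
                      straight_len = gy$straight_len_um * um,
                      converging_len = gy$converging_len_um * um,
                      inlet_len = gy$inlet_len_um * um,
                      height = gy$height_um * um,
                      nodes_per_l = gy$nodes_per_l)
  }
  fl <- do.call(fluid_model, cfg$fluid)
  ce <- cfg$cell
  rn <- cfg$run
  transit_config(geom, fl, U = rn$U, Ca = ce$Ca, C = ce$C,
                 eta = if (is.null(ce$eta)) 0 else ce$eta,
                 lambda = if (is.null(ce$lambda)) 1 else ce$lambda,
                 confinement = ce$confinement,
                 an_over_a = if (is.null(ce$an_over_a)) 0.5 else ce$an_over_a,
                 d_oc_z = if (is.null(rn$d_oc_z)) 0 else rn$d_oc_z,
                 d_oc_y = if (is.null(rn$d_oc_y)) 0 else rn$d_oc_y,
                 release_x = if (is.null(rn$release_x_um)) NULL else
                   rn$release_x_um * um,
                 mesh_subdiv = if (is.null(rn$mesh_subdiv)) 3 else
                   rn$mesh_subdiv,
                 mesh_subdiv_nucleus = if (is.null(rn$mesh_subdiv_nucleus)) 2
                   else rn$mesh_subdiv_nucleus,
                 dt_safety = if (is.null(rn$dt_safety)) 0.3 else rn$dt_safety,
                 record_every = if (is.null(rn$record_every)) 40 else
                   rn$record_every,
                 max_tstar = if (is.null(rn$max_tstar)) 20 else rn$max_tstar)
}
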