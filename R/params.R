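#' Suspending-fluid rheology model
#'
#' Describes the cell-suspension buffer as a truncated power-law
#' (shear-thinning) liquid, \eqn{\mu = K (\dot\gamma/\dot\gamma_0)^{\alpha-1}},
#' together with its density and the characteristic cross-section-average
#' viscosity \eqn{\mu_0} used to form dimensionless groups.
#'
#' @param K consistency index (Pa s).
#' @param alpha power-law index (dimensionless, 0 < alpha <= 1 here).
#' @param gamma0 reference shear rate (1/s).
#' @param gamma_min,gamma_max truncation bounds for the local shear rate
#'   (1/s); outside this window the viscosity is evaluated at the bound.
#' @param rho fluid density (kg/m^3).
#' @param mu0 characteristic viscosity (Pa s), the cross-section average of
#'   the fully developed duct flow.  Taken as an input (see
#'   [mu0_cross_section()] for a numerical estimate).
#' @return An object of class `fluid_model`.
#' @examples
#' fl <- fluid_model()
#' power_law_viscosity(100, fl)
#' @export
fluid_model <- function(K = 0.053, alpha = 0.95, gamma0 = 1,
                        gamma_min = 0.01, gamma_max = 1e6,
                        rho = 1060, mu0 = 0.0327) {
  stopifnot(is.numeric(K), K > 0, is.finite(K))
  stopifnot(alpha > 0, alpha <= 1)
  stopifnot(gamma0 > 0, gamma_min >= 0, gamma_min < gamma_max)
  stopifnot(rho > 0, mu0 > 0)
  structure(list(K = K, alpha = alpha, gamma0 = gamma0,
                 gamma_min = gamma_min, gamma_max = gamma_max,
                 rho = rho, mu0 = mu0),
            class = "fluid_model")
}

#' Truncated power-law viscosity
#'
#' Evaluates \eqn{\mu = K(\hat\gamma/\dot\gamma_0)^{\alpha-1}} with the shear
#' rate clamped to the truncation window of the fluid model, so the viscosity
#' stays bounded as \eqn{\dot\gamma \to 0}.
#'
#' @param gamma_dot local shear rate (1/s), vectorised; must be finite and
#'   non-negative.
#' @param fluid a [fluid_model()].
#' @return viscosity (Pa s), same length as `gamma_dot`.
#' @export
power_law_viscosity <- function(gamma_dot, fluid = fluid_model()) {
  if (!is.numeric(gamma_dot) || any(!is.finite(gamma_dot)))
    stop("'gamma_dot' must be finite and numeric")
  if (any(gamma_dot < 0)) stop("'gamma_dot' must be non-negative")
  g <- pmin(pmax(gamma_dot, fluid$gamma_min), fluid$gamma_max)
  fluid$K * (g / fluid$gamma0)^(fluid$alpha - 1)
}

#' Cell (compound capsule) mechanical parameters
#'
#' Dimensional parameters of the three-layer cell model: a Skalak membrane
#' with shear modulus `Gs` and hardness `C` (area-dilatation modulus
#' `Ks = (1 + 2C) Gs`), surface shear viscosity `mu_s`, Helfrich bending
#' modulus `kc` (default the small regularising value `0.001 Gs a^2`),
#' Newtonian cytoplasm of viscosity `mu_c`, and a nucleus capsule of radius
#' `an_over_a * a` whose membrane moduli are `Gsn_factor` times those of the
#' cell membrane (hence the same hardness parameter) and which carries no
#' membrane viscosity (it is purely hyperelastic).
#'
#' @param a cell radius (m).
#' @param Gs membrane shear elastic modulus (N/m).
#' @param C hardness parameter (dimensionless).
#' @param mu_s membrane shear viscosity (N s/m).
#' @param mu_s_dil membrane dilatational viscosity (N s/m); neglected by
#'   default.
#' @param kc bending modulus (J); `NULL` means `0.001 * Gs * a^2`.
#' @param c0 spontaneous curvature (1/m).
#' @param mu_c cytoplasm viscosity (Pa s).
#' @param an_over_a nucleus-to-cell radius ratio.
#' @param Gsn_factor nucleus membrane stiffness multiplier.
#' @return An object of class `cell_params` with derived fields `Ks`, `kc`,
#'   `Gsn`, `Ksn`, `kcn`, `an`.
#' @export
cell_params <- function(a, Gs, C, mu_s = 0, mu_s_dil = 0, kc = NULL, c0 = 0,
                        mu_c = NULL, an_over_a = 0.5, Gsn_factor = 2) {
  stopifnot(a > 0, Gs > 0, C >= 0, mu_s >= 0, mu_s_dil >= 0)
  if (is.null(kc)) kc <- 0.001 * Gs * a^2
  stopifnot(kc >= 0, an_over_a >= 0, an_over_a < 1, Gsn_factor > 0)
  an <- an_over_a * a
  Gsn <- Gsn_factor * Gs
  structure(list(a = a, Gs = Gs, C = C, Ks = (1 + 2 * C) * Gs,
                 mu_s = mu_s, mu_s_dil = mu_s_dil, kc = kc, c0 = c0,
                 mu_c = mu_c, an_over_a = an_over_a, an = an,
                 Gsn_factor = Gsn_factor, Gsn = Gsn,
                 Ksn = (1 + 2 * C) * Gsn,
                 kcn = if (an > 0) 0.001 * Gsn * an^2 else 0),
            class = "cell_params")
}

#' Channel specification
#'
#' Flow-condition container for a square-cross-section microchannel: width
#' `l`, volumetric flow rate `Q` and/or mean speed `U = Q / l^2`.
#'
#' @param kind `"constricted"` or `"cross_slot"`.
#' @param l channel width (m); for the cross-slot this is the branch width.
#' @param Q volumetric flow rate (m^3/s); for the cross-slot, per branch.
#' @param U mean duct speed (m/s); derived from `Q` when omitted.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(kind = c("constricted", "cross_slot"), l, Q = NULL,
                         U = NULL) {
  kind <- match.arg(kind)
  stopifnot(l > 0)
  if (is.null(U)) {
    if (is.null(Q)) stop("give one of 'Q' or 'U'")
    U <- mean_duct_speed(Q, l)
  } else if (is.null(Q)) {
    Q <- U * l^2
  }
  structure(list(kind = kind, l = l, Q = Q, U = U), class = "channel_spec")
}

#' Mean speed in a square duct
#'
#' @param Q volumetric flow rate (m^3/s).
#' @param l duct width (m).
#' @return mean speed `Q / l^2` (m/s).
#' @export
mean_duct_speed <- function(Q, l) {
  stopifnot(l > 0, Q >= 0)
  Q / l^2
}

#' Dimensionless groups of a cell-transit problem
#'
#' Forms the groups governing the deformation of a compound capsule in a
#' microchannel: the capillary number \eqn{Ca = \mu_0 U / G_s}, hardness
#' parameter \eqn{C}, dimensionless membrane viscosity
#' \eqn{\eta = \mu_s/(\mu_0 a)}, viscosity ratio \eqn{\lambda = \mu_c/\mu_0},
#' confinement ratio \eqn{2a/l}, nucleus size ratio and the channel Reynolds
#' number \eqn{Re = \rho U l / \mu_0}.
#'
#' @param fluid a [fluid_model()].
#' @param cell a [cell_params()].
#' @param chan a [channel_spec()].
#' @return A list of class `dimensionless_groups` with fields `Ca`, `C`,
#'   `eta`, `lambda`, `confinement`, `an_over_a`, `Re`.
#' @export
dimensionless_groups <- function(fluid, cell, chan) {
  stopifnot(inherits(fluid, "fluid_model"), inherits(cell, "cell_params"),
            inherits(chan, "channel_spec"))
  if (cell$Gs <= 0 || fluid$mu0 <= 0) stop("Gs and mu0 must be positive")
  lam <- if (is.null(cell$mu_c)) 1 else cell$mu_c / fluid$mu0
  structure(list(
    Ca = fluid$mu0 * chan$U / cell$Gs,
    C = cell$C,
    eta = cell$mu_s / (fluid$mu0 * cell$a),
    lambda = lam,
    confinement = 2 * cell$a / chan$l,
    an_over_a = cell$an_over_a,
    Re = fluid$rho * chan$U * chan$l / fluid$mu0
  ), class = "dimensionless_groups")
}

#' Dimensional membrane properties from dimensionless groups
#'
#' Inverts the dimensionless groups at given flow conditions:
#' \eqn{G_s = \mu_0 U / Ca}, \eqn{K_s = (1+2C) G_s},
#' \eqn{\mu_s = \eta\,\mu_0\,a}.
#'
#' @param Ca capillary number (> 0).
#' @param C hardness parameter.
#' @param eta dimensionless membrane viscosity.
#' @param fluid a [fluid_model()] supplying `mu0`.
#' @param U mean duct speed (m/s).
#' @param a cell radius (m).
#' @return list with `Gs`, `Ks` (N/m) and `mu_s` (N s/m).
#' @export
to_dimensional <- function(Ca, C, eta, fluid, U, a) {
  if (any(Ca <= 0)) stop("'Ca' must be positive")
  stopifnot(U > 0, a > 0)
  Gs <- fluid$mu0 * U / Ca
  list(Gs = Gs, Ks = (1 + 2 * C) * Gs, mu_s = eta * fluid$mu0 * a)
}

#' Half-increment uncertainty of inferred membrane properties
#'
#' The inverse fit scans a finite grid; the parameter uncertainty is taken as
#' half a grid increment on each dimensionless group and propagated to the
#' dimensional moduli: \eqn{\delta G_s = G_s\,(\delta Ca/2)/Ca},
#' \eqn{\delta \mu_s = \mu_s\,(\delta\eta/2)/\eta} (one half-increment bound
#' when \eqn{\eta = 0}), and for the area-dilatation modulus the two
#' contributions combine in quadrature:
#' \eqn{\delta K_s = \sqrt{(2 G_s\,\delta C/2)^2 + ((1+2C)\,\delta G_s)^2}}.
#'
#' @param Ca,C,eta best-fit dimensionless values (on the scan grid).
#' @param dCa,dC,deta full grid increments.
#' @param fluid a [fluid_model()].
#' @param U mean duct speed (m/s).
#' @param a cell radius (m).
#' @return list with the dimensional values and their uncertainties
#'   (`Gs`, `dGs`, `Ks`, `dKs`, `mu_s`, `dmu_s`).
#' @export
propagate_uncertainty <- function(Ca, C, eta, dCa = 0.1, dC = 1, deta = 5,
                                  fluid = fluid_model(), U, a) {
  if (Ca <= 0) stop("'Ca' must be positive")
  dim <- to_dimensional(Ca, C, eta, fluid, U, a)
  dGs <- dim$Gs * (dCa / 2) / Ca
  dKs <- sqrt((2 * dim$Gs * dC / 2)^2 + ((1 + 2 * C) * dGs)^2)
  dmu_s <- if (eta > 0) dim$mu_s * (deta / 2) / eta else
    (deta / 2) * fluid$mu0 * a
  c(dim, list(dGs = dGs, dKs = dKs, dmu_s = dmu_s))
}

#' Cross-section-average viscosity of fully developed duct flow
#'
#' Numerical estimate of the average power-law viscosity over the square duct
#' cross section, for comparison with a quoted characteristic viscosity
#' \eqn{\mu_0}.  The fully developed velocity field is computed on a grid by
#' Picard iteration of the variable-viscosity Poisson problem driven to the
#' requested mean speed; the local shear rate then gives the viscosity field,
#' averaged either uniformly over the area or weighted by the local speed.
#'
#' @param fluid a [fluid_model()].
#' @param U target mean speed (m/s).
#' @param l duct width (m).
#' @param n grid points across the duct.
#' @param weighting `"area"` or `"flow"` (velocity-weighted).
#' @return average viscosity (Pa s).
#' @export
mu0_cross_section <- function(fluid, U, l, n = 48,
                              weighting = c("area", "flow")) {
  weighting <- match.arg(weighting)
  h <- l / n
  yz <- (seq_len(n) - 0.5) * h
  u <- matrix(0, n, n)
  G <- 1  # pressure gradient magnitude, rescaled each iteration
  for (it in 1:60) {
    # shear rate from central differences (zero velocity at walls)
    up <- rbind(u[-1, ], 0); um <- rbind(0, u[-n, ])
    lp <- cbind(u[, -1], 0); lm <- cbind(0, u[, -n])
    duy <- (up - um) / (2 * h); duz <- (lp - lm) / (2 * h)
    gd <- sqrt(duy^2 + duz^2)
    mu <- power_law_viscosity(pmax(gd, fluid$gamma_min), fluid)
    # Jacobi update of div(mu grad u) = -G with harmonic-mean face viscosity
    muyp <- rbind((2 * mu[-1, ] * mu[-n, ]) / (mu[-1, ] + mu[-n, ]), mu[n, ])
    muym <- rbind(mu[1, ], (2 * mu[-1, ] * mu[-n, ]) / (mu[-1, ] + mu[-n, ]))
    muzp <- cbind((2 * mu[, -1] * mu[, -n]) / (mu[, -1] + mu[, -n]), mu[, n])
    muzm <- cbind(mu[, 1], (2 * mu[, -1] * mu[, -n]) / (mu[, -1] + mu[, -n]))
    for (s in 1:40) {
      up <- rbind(u[-1, ], 0); um <- rbind(0, u[-n, ])
      lp <- cbind(u[, -1], 0); lm <- cbind(0, u[, -n])
      u <- (muyp * up + muym * um + muzp * lp + muzm * lm + G * h^2) /
        (muyp + muym + muzp + muzm)
    }
    sc <- U / mean(u)
    u <- u * sc; G <- G * sc
  }
  up <- rbind(u[-1, ], 0); um <- rbind(0, u[-n, ])
  lp <- cbind(u[, -1], 0); lm <- cbind(0, u[, -n])
  gd <- sqrt(((up - um) / (2 * h))^2 + ((lp - lm) / (2 * h))^2)
  mu <- power_law_viscosity(pmax(gd, fluid$gamma_min), fluid)
  if (weighting == "area") mean(mu) else sum(mu * u) / sum(u)
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups:\n")
  cat(sprintf("  Ca = %.4g  C = %.4g  eta = %.4g  lambda = %.4g\n",
              x$Ca, x$C, x$eta, x$lambda))
  cat(sprintf("  2a/l = %.4g  an/a = %.4g  Re = %.4g\n",
              x$confinement, x$an_over_a, x$Re))
  invisible(x)
}
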