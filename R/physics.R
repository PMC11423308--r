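#' Universal REDOR dephasing curve
#'
#' Closed-form powder-averaged REDOR dephasing fraction for an isolated
#' heteronuclear spin-1/2 pair under ideal, instantaneous pi pulses applied
#' every half rotor period.  The curve depends on the effective dipolar
#' coupling constant \eqn{d} (Hz) and the dephasing time \eqn{t} (s) only
#' through the dimensionless product \eqn{\lambda = d t}:
#' \deqn{\Delta S/S_0(\lambda) = 1 - \frac{\sqrt{2}\pi}{4}
#'   J_{1/4}(\sqrt{2}\lambda)\, J_{-1/4}(\sqrt{2}\lambda),}
#' the quarter-order Bessel-function solution of the powder average of the
#' rotor-synchronized first-order MAS dipolar phase.  The curve rises
#' monotonically to a first maximum of about 1.04 near \eqn{\lambda \approx
#' 1.68}, then oscillates about 1 with an envelope decaying roughly as
#' \eqn{1/(2\lambda)}.
#'
#' @param lambda Non-negative numeric vector, the product \eqn{d t}
#'   (dimensionless).
#' @return Dephasing fraction(s) \eqn{\Delta S/S_0 = 1 - S/S_0}, in
#'   \eqn{[0, \sim 1.05]}.
#' @examples
#' redor_universal(0)            # no dephasing at t = 0
#' redor_universal(663 * 571e-6) # helix-average coupling at 571 us
#' @seealso [redor_powder()] for the brute-force powder-integration oracle.
#' @export
redor_universal <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)))
    stop("'lambda' must be finite numeric")
  if (any(lambda < 0))
    stop("'lambda' must be non-negative (it is the product d*t)")
  out <- numeric(length(lambda))
  pos <- lambda > 0
  x <- sqrt(2) * lambda[pos]
  out[pos] <- 1 - (sqrt(2) * pi / 4) * besselJ(x, 0.25) * besselJ(x, -0.25)
  out
}

#' Crystallite orientation grid for powder averaging
#'
#' Builds a two-angle powder grid: Gauss--Legendre quadrature in
#' \eqn{\cos\beta} crossed with a uniform midpoint grid in \eqn{\gamma}.
#' The scheme is deterministic, so convergence can be tested by refining
#' the grid.
#'
#' @param n_beta Number of Gauss--Legendre nodes in \eqn{\cos\beta}.
#' @param n_gamma Number of uniform \eqn{\gamma} points on \eqn{[0, 2\pi)}.
#' @return A `powder_grid`: data frame with columns `beta`, `gamma`
#'   (radians) and `weight` (summing to 1), with the scheme name stored in
#'   `attr(, "scheme_name")`.
#' @export
powder_grid <- function(n_beta = 64L, n_gamma = 64L) {
  if (n_beta < 1L || n_gamma < 1L) stop("grid dimensions must be positive")
  gl <- pracma::gaussLegendre(n_beta, -1, 1)
  beta <- acos(gl$x)
  gamma <- (seq_len(n_gamma) - 0.5) * 2 * pi / n_gamma
  g <- data.frame(
    beta   = rep(beta, times = n_gamma),
    gamma  = rep(gamma, each = n_beta),
    weight = rep(gl$w / 2 / n_gamma, times = n_gamma)
  )
  attr(g, "scheme_name") <- sprintf("gauss_legendre_%dx%d", n_beta, n_gamma)
  class(g) <- c("powder_grid", "data.frame")
  g
}

validate_powder_grid <- function(grid) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty powder grid")
  if (!all(c("beta", "gamma", "weight") %in% names(grid)))
    stop("powder grid needs columns beta, gamma, weight")
  if (abs(sum(grid$weight) - 1) > 1e-9)
    stop("powder grid weights must sum to 1")
  if (any(grid$beta < 0 | grid$beta > pi) ||
      any(grid$gamma < 0 | grid$gamma >= 2 * pi))
    stop("powder grid angles out of range")
  invisible(grid)
}

# Accumulated REDOR phase for one crystallite over dephasing time t:
# sign-toggled integral of the first-order MAS dipolar frequency, with pi
# pulses every half rotor period.  Per full rotor period the 2*omega_r term
# integrates to zero and the omega_r term leaves
#   dPhi = 4*sqrt(2) * d * t * sin(beta)*cos(beta)*sin(gamma)
# (t an even multiple of tau_r; the expression is exact in that case and is
# the rotor-period average otherwise).
redor_phase <- function(d, t, beta, gamma) {
  4 * sqrt(2) * d * t * sin(beta) * cos(beta) * sin(gamma)
}

#' Powder-averaged REDOR dephasing by explicit integration
#'
#' First-principles oracle for [redor_universal()]: accumulates the
#' rotor-synchronized, sign-toggled first-order MAS dipolar phase for every
#' crystallite and powder-averages \eqn{\cos\Delta\Phi}.  Converges to the
#' closed form as the grid is refined.
#'
#' @param d Dipolar coupling constant, Hz (scalar, >= 0).
#' @param t Dephasing time(s), s (vector, >= 0); even multiples of the rotor
#'   period in a real experiment.
#' @param grid A [powder_grid()].
#' @return Dephasing fraction(s) \eqn{1 - \langle\cos\Delta\Phi\rangle}.
#' @export
redor_powder <- function(d, t, grid = powder_grid()) {
  if (length(d) != 1L || d < 0) stop("'d' must be a single non-negative Hz value")
  if (any(t < 0)) stop("'t' must be non-negative")
  validate_powder_grid(grid)
  geom <- sin(grid$beta) * cos(grid$beta) * sin(grid$gamma)
  vapply(t, function(ti) {
    1 - sum(grid$weight * cos(4 * sqrt(2) * d * ti * geom))
  }, numeric(1))
}

#' Spin cluster for multi-spin REDOR simulation
#'
#' One observed spin (e.g. a backbone Calpha) plus its heteronuclear dipolar
#' partners, each given as a coupling constant and a unit bond vector in a
#' common molecular frame.
#'
#' @param couplings Numeric vector of coupling constants, Hz (>= 0).
#' @param vectors Matrix with one row per partner (3 columns), or a single
#'   length-3 vector; each row must have unit norm within 1e-9.
#' @param heteronuclear Logical; homonuclear partners are not supported
#'   (their dephasing does not commute with the heteronuclear phases).
#' @return A `spin_cluster` object.
#' @export
spin_cluster <- function(couplings, vectors, heteronuclear = TRUE) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  vectors <- as.matrix(vectors)
  if (length(couplings) < 1L) stop("cluster needs at least one coupling")
  if (nrow(vectors) != length(couplings) || ncol(vectors) != 3L)
    stop("'vectors' must be one unit 3-vector per coupling")
  if (any(couplings < 0)) stop("coupling constants must be >= 0")
  norms <- sqrt(rowSums(vectors^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("bond vectors must have unit norm (within 1e-9)")
  if (!isTRUE(heteronuclear))
    stop("homonuclear partners are not supported: ",
         "their recoupling requires full spin dynamics")
  structure(list(couplings = as.numeric(couplings), vectors = vectors),
            class = "spin_cluster")
}

#' Multi-spin REDOR dephasing under ideal pulses
#'
#' For an observed spin coupled to several heteronuclear spin-1/2 partners
#' the per-partner dephasing Hamiltonians commute, and each partner is
#' independently up or down, so the powder-averaged signal factorizes per
#' crystallite into \eqn{\langle\prod_k \cos\Delta\Phi_k\rangle}.  Each
#' crystallite orientation rotates the molecular frame into the rotor
#' frame; because the relative azimuths of the bond vectors matter, the
#' two-angle powder grid is augmented internally with a uniform average
#' over the third Euler angle.  A single-partner cluster reduces exactly
#' to [redor_powder()].
#'
#' @param cluster A [spin_cluster()].
#' @param t Dephasing time(s), s.
#' @param grid A [powder_grid()] for the (beta, gamma) average.
#' @param n_alpha Number of points in the internal average over the initial
#'   rotation about the molecular z axis (only the relative azimuths of
#'   multiple partners depend on it).
#' @return Dephasing fraction(s) \eqn{1 - \langle\cos\sum\Delta\Phi\rangle}.
#' @export
redor_multispin <- function(cluster, t, grid = powder_grid(),
                            n_alpha = 16L) {
  if (!inherits(cluster, "spin_cluster")) stop("'cluster' must be a spin_cluster")
  validate_powder_grid(grid)
  if (any(t < 0)) stop("'t' must be non-negative")
  d <- cluster$couplings
  v <- cluster$vectors
  alphas <- if (nrow(v) > 1L) (seq_len(n_alpha) - 0.5) * 2 * pi / n_alpha else 0
  cb <- cos(grid$beta); sb <- sin(grid$beta)
  cg <- cos(grid$gamma); sg <- sin(grid$gamma)
  vapply(t, function(ti) {
    acc <- 0
    for (a in alphas) {
      ca <- cos(a); sa <- sin(a)
      prod_cos <- 1
      for (k in seq_along(d)) {
        # R = Rz(gamma) Ry(beta) Rz(alpha) applied to bond vector v_k
        x1 <- ca * v[k, 1] - sa * v[k, 2]
        y1 <- sa * v[k, 1] + ca * v[k, 2]
        z1 <- v[k, 3]
        x2 <- cb * x1 + sb * z1
        z2 <- -sb * x1 + cb * z1
        y3 <- sg * x2 + cg * y1
        # rotor-frame polar/azimuthal geometry factor sin(th)cos(th)sin(phi)
        # for unit vectors: cos(th) = z2, sin(th)sin(phi) = y3
        prod_cos <- prod_cos * cos(4 * sqrt(2) * ti * d[k] * z2 * y3)
      }
      acc <- acc + sum(grid$weight * prod_cos)
    }
    1 - acc / length(alphas)
  }, numeric(1))
}

# lambda at the first maximum of the universal curve (initial rise ends here)
.redor_lambda_max <- function() {
  stats::optimize(redor_universal, c(1, 2.5), maximum = TRUE)$maximum
}

#' REDOR filter-time selection
#'
#' Smallest dephasing time, rounded up to an even multiple of the rotor
#' period, at which the universal dephasing curve reaches a target fraction.
#' Used to choose the dephasing time of a REDOR filter so that crosspeaks of
#' rigid sites (with coupling `d`) are suppressed to the target level while
#' mobile sites survive.  The search is restricted to the initial rise of
#' the curve (up to its first maximum, about 1.04).
#'
#' @param d Effective dipolar coupling constant, Hz (> 0).
#' @param target_fraction Target dephasing fraction in `[0, 1)`.
#' @param rotor_period MAS rotor period, s (> 0).
#' @return Dephasing time in seconds, an even multiple of `rotor_period`
#'   (0 for a zero target).
#' @export
redor_filter_time <- function(d, target_fraction, rotor_period) {
  if (d <= 0) stop("'d' must be positive")
  if (rotor_period <= 0) stop("'rotor_period' must be positive")
  if (target_fraction < 0 || target_fraction >= 1)
    stop("'target_fraction' must be in [0, 1)")
  if (target_fraction == 0) return(0)
  lam_max <- .redor_lambda_max()
  f_max <- redor_universal(lam_max)
  if (target_fraction > f_max)
    stop(sprintf(
      "target fraction %.3f exceeds the achievable maximum %.3f on the initial rise",
      target_fraction, f_max))
  lam <- stats::uniroot(function(l) redor_universal(l) - target_fraction,
                        c(1e-12, lam_max), tol = 1e-12)$root
  t_raw <- lam / d
  2 * rotor_period * ceiling(t_raw / (2 * rotor_period) - 1e-9)
}
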