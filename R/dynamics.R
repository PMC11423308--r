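# CODATA gyromagnetic ratios, rad s^-1 T^-1 (sign kept; magnitudes used for d)
.gyromag <- c("1H" = 2.6752218744e8,
              "13C" = 6.728284e7,
              "15N" = -2.7126e7)

.hbar <- 1.054571817e-34   # J s
.mu0_over_4pi <- 1e-7      # T m / A

#' Rigid-limit heteronuclear dipolar coupling constant
#'
#' Inverse-cube distance law for the dipolar coupling between two nuclei,
#' \deqn{d = \frac{\mu_0}{4\pi} \frac{\gamma_I \gamma_S \hbar}{2\pi r^3},}
#' reported as a positive magnitude in Hz.  For a 1.45 Angstrom Calpha--N
#' bond this gives the 1005 Hz rigid limit used to normalize backbone order
#' parameters; 1.40 Angstrom (tryptophan Ce2--Ne1) gives 1116 Hz and 1.32
#' Angstrom (amide Cd--Ne2) 1317 Hz.
#'
#' @param r Internuclear distance in Angstrom (> 0).
#' @param nuclei Character vector of two isotope labels among `"1H"`,
#'   `"13C"`, `"15N"`.
#' @return Coupling constant in Hz (positive magnitude, unrounded).
#' @examples
#' round(rigid_coupling(1.45))  # 1005
#' round(rigid_coupling(1.40))  # 1116
#' @export
rigid_coupling <- function(r, nuclei = c("13C", "15N")) {
  if (any(r <= 0)) stop("'r' must be positive (Angstrom)")
  if (length(nuclei) != 2L) stop("'nuclei' must name two isotopes")
  unknown <- setdiff(nuclei, names(.gyromag))
  if (length(unknown))
    stop("unknown isotope(s): ", paste(unknown, collapse = ", "))
  g <- abs(.gyromag[nuclei])
  .mu0_over_4pi * g[[1]] * g[[2]] * .hbar / (2 * pi * (r * 1e-10)^3)
}

#' Order parameter from a fitted coupling
#'
#' The order parameter is the ratio of the motionally averaged coupling to
#' its rigid limit, \eqn{S = d / d_{rigid}}; its uncertainty scales the
#' coupling uncertainty by the same factor.  Values above 1 (possible with
#' noise) are retained but flagged with a warning.
#'
#' @param d_hat Fitted effective coupling, Hz (>= 0), or a `coupling_fit`.
#' @param d_rigid Rigid-limit coupling, Hz (> 0).
#' @param d_sigma Coupling uncertainty, Hz (ignored when `d_hat` is a
#'   `coupling_fit`).
#' @return List with elements `S` and `sigma`.
#' @export
order_parameter <- function(d_hat, d_rigid, d_sigma = 0) {
  if (inherits(d_hat, "coupling_fit")) {
    d_sigma <- d_hat$d_sigma
    d_hat <- d_hat$d_hat
  }
  if (d_rigid <= 0) stop("'d_rigid' must be positive")
  if (d_hat < 0) stop("'d_hat' must be non-negative")
  S <- d_hat / d_rigid
  if (S > 1) warning(sprintf("order parameter %.2f exceeds 1 (flagged)", S))
  list(S = S, sigma = d_sigma / d_rigid)
}

#' Cone-model motional amplitudes from an order parameter
#'
#' `amplitude_on_cone()` inverts the diffusion-on-a-cone relation
#' \eqn{S = P_2(\cos\theta) = (3\cos^2\theta - 1)/2} on \eqn{[0, 90]}
#' degrees; `amplitude_in_cone()` inverts the diffusion-in-a-cone
#' (wobbling) relation \eqn{S = \cos\theta(1 + \cos\theta)/2} via its
#' quadratic in \eqn{\cos\theta} (positive root).  Both take the absolute
#' value of `S`, since the measurement is insensitive to the sign of the
#' interaction; the negative-sign on-cone branch (\eqn{\theta > 54.7}
#' degrees) can be requested explicitly.
#'
#' @param S Order parameter(s), |S| <= 1.
#' @param branch For the on-cone model: `"positive"` takes
#'   \eqn{P_2(\cos\theta) = |S|}; `"negative"` solves
#'   \eqn{P_2(\cos\theta) = -|S|} (requires |S| <= 0.5).
#' @return Cone (semi-)angle(s) in degrees, in `[0, 90]`.
#' @examples
#' amplitude_on_cone(0.66)  # ~28.4 deg; the helix-average amplitude
#' amplitude_in_cone(0.16)  # ~75.2 deg; maximal angle for the terminal residue
#' @export
amplitude_on_cone <- function(S, branch = c("positive", "negative")) {
  branch <- match.arg(branch)
  a <- abs(S)
  if (any(a > 1 + 1e-12)) stop("|S| must be <= 1")
  a <- pmin(a, 1)
  cos2 <- if (branch == "positive") (2 * a + 1) / 3 else {
    if (any(a > 0.5 + 1e-12))
      stop("negative branch requires |S| <= 0.5")
    (1 - 2 * a) / 3
  }
  acos(sqrt(cos2)) * 180 / pi
}

#' @rdname amplitude_on_cone
#' @export
amplitude_in_cone <- function(S) {
  a <- abs(S)
  if (any(a > 1 + 1e-12)) stop("|S| must be <= 1")
  a <- pmin(a, 1)
  costh <- (-1 + sqrt(1 + 8 * a)) / 2
  acos(pmin(costh, 1)) * 180 / pi
}

#' Forward cone-model order parameters
#'
#' Forward evaluation of the two cone models at a given (semi-)angle, used
#' for round-trip checks and for predicting order parameters from bond
#' geometry: `order_on_cone()` returns \eqn{P_2(\cos\theta)} and
#' `order_in_cone()` returns \eqn{\cos\theta(1+\cos\theta)/2}.
#'
#' @param theta_deg Cone angle(s) in degrees.
#' @return Order parameter(s); `order_on_cone()` may be negative.
#' @export
order_on_cone <- function(theta_deg) {
  c2 <- cos(theta_deg * pi / 180)^2
  (3 * c2 - 1) / 2
}

#' @rdname order_on_cone
#' @export
order_in_cone <- function(theta_deg) {
  ct <- cos(theta_deg * pi / 180)
  ct * (1 + ct) / 2
}

#' Per-site dynamics table
#'
#' Assembles fitted couplings into a per-site table of order parameters and
#' cone-model amplitudes, and summarizes the helical plateau by the mean
#' order parameter and its standard error over a residue range.
#'
#' @param fits Named list of `coupling_fit` objects; names are site ids.
#' @param info Data frame with columns `site_id`, `residue`, `bond` and
#'   `d_rigid` (Hz), one row per site.
#' @param helix_range Residue range (inclusive) over which the plateau mean
#'   is computed; the coat-protein helix spans residues 6--50.
#' @return A `site_dynamics` data frame with columns `site_id`, `residue`,
#'   `bond`, `d_hat`, `d_sigma`, `S`, `S_sigma`, `theta_on_deg`,
#'   `theta_in_deg`, `chi2_reduced`, `flagged`.  The helix summary is in
#'   `attr(, "helix_mean")` / `attr(, "helix_se")`.
#' @export
build_site_table <- function(fits, info, helix_range = c(6, 50)) {
  stopifnot(is.list(fits), !is.null(names(fits)),
            all(c("site_id", "residue", "bond", "d_rigid") %in% names(info)))
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    m <- match(id, info$site_id)
    if (is.na(m)) {
      warning("no rigid pair for site '", id, "'; skipped")
      return(NULL)
    }
    op <- withCallingHandlers(
      order_parameter(f$d_hat, info$d_rigid[m], f$d_sigma),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(site_id = id, residue = info$residue[m], bond = info$bond[m],
               d_hat = f$d_hat, d_sigma = f$d_sigma,
               S = op$S, S_sigma = op$sigma,
               theta_on_deg = amplitude_on_cone(min(op$S, 1)),
               theta_in_deg = amplitude_in_cone(min(op$S, 1)),
               chi2_reduced = f$chi2_reduced,
               flagged = op$S > 1)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$residue, tab$bond), ]
  rownames(tab) <- NULL
  in_helix <- tab$residue >= helix_range[1] & tab$residue <= helix_range[2]
  attr(tab, "helix_range") <- helix_range
  attr(tab, "helix_mean") <- mean(tab$S[in_helix])
  attr(tab, "helix_se") <- stats::sd(tab$S[in_helix]) / sqrt(sum(in_helix))
  class(tab) <- c("site_dynamics", "data.frame")
  tab
}
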