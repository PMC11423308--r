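#' Synthetic-study configuration
#'
#' Parameters of the synthetic data generator.  The defaults emulate the
#' study conditions of the coat-protein experiments: a 50-residue protein
#' whose flexible N-terminus ramps from an order parameter of 0.16 at
#' residue 1 up to a uniform helical plateau of 0.66 from residue 6 onward;
#' a 71.4 microsecond rotor period (14 kHz MAS) with dephasing times of
#' {6, 8, 16, 24} rotor periods (429, 571, 1143, 1714 microseconds); a
#' signal-to-noise ratio of 10; three crosspeaks reporting on each
#' Calpha--N bond; and about 4 percent of sites emitted as
#' ambiguity-paired records.
#'
#' @param n_residues Number of residues.
#' @param helix_start First residue of the helical plateau.
#' @param plateau_S Plateau order parameter.
#' @param terminal_S Order parameter of residue 1.
#' @param rotor_period MAS rotor period, s.
#' @param dephasing_times Dephasing times, s; each must be a positive even
#'   multiple of `rotor_period`.
#' @param snr Signal-to-noise ratio of the reference intensity.
#' @param crosspeaks_per_site Replicate crosspeaks per bond.
#' @param ambiguous_fraction Fraction of sites paired into ambiguous
#'   (overlapped) records.
#' @param plateau_jitter SD of Gaussian jitter on the plateau order
#'   parameters (0 = exactly uniform).
#' @param seed Integer seed; recorded in all outputs.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_residues = 50L, helix_start = 6L,
                             plateau_S = 0.66, terminal_S = 0.16,
                             rotor_period = 71.4e-6,
                             dephasing_times = c(6, 8, 16, 24) * 71.4e-6,
                             snr = 10, crosspeaks_per_site = 3L,
                             ambiguous_fraction = 0.04,
                             plateau_jitter = 0, seed = 1L) {
  if (!(terminal_S > 0 && terminal_S <= plateau_S && plateau_S <= 1))
    stop("need 0 < terminal_S <= plateau_S <= 1")
  if (helix_start < 2L || helix_start > n_residues)
    stop("'helix_start' must lie inside the chain")
  mult <- dephasing_times / rotor_period
  if (any(dephasing_times <= 0) ||
      any(abs(mult / 2 - round(mult / 2)) > 1e-6))
    stop("dephasing times must be positive even multiples of the rotor period")
  structure(list(n_residues = as.integer(n_residues),
                 helix_start = as.integer(helix_start),
                 plateau_S = plateau_S, terminal_S = terminal_S,
                 rotor_period = rotor_period,
                 dephasing_times = dephasing_times, snr = snr,
                 crosspeaks_per_site = as.integer(crosspeaks_per_site),
                 ambiguous_fraction = ambiguous_fraction,
                 plateau_jitter = plateau_jitter, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' True per-residue order-parameter profile
#'
#' Residues 1 to `helix_start - 1` ramp linearly and monotonically from
#' `terminal_S` up to the plateau; residues from `helix_start` onward sit
#' at `plateau_S` (plus optional jitter).  True couplings follow from the
#' 1.45 Angstrom Calpha--N rigid limit, `d_true = S * rigid_coupling(1.45)`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `residue`, `S_true`, `d_true` (Hz).
#' @export
make_profile <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  hs <- config$helix_start
  ramp <- config$terminal_S +
    (config$plateau_S - config$terminal_S) *
    (seq_len(hs - 1L) - 1L) / (hs - 1L)
  S <- c(ramp, rep(config$plateau_S, config$n_residues - hs + 1L))
  if (config$plateau_jitter > 0) {
    set.seed(config$seed + 1L)
    idx <- hs:config$n_residues
    S[idx] <- pmin(pmax(
      S[idx] + stats::rnorm(length(idx), 0, config$plateau_jitter),
      config$terminal_S), 1)
  }
  data.frame(residue = seq_len(config$n_residues), S_true = S,
             d_true = S * rigid_coupling(1.45))
}

#' Synthetic crosspeak intensity tables
#'
#' Emulates the intensity tables produced by crosspeak analysis of the
#' pseudo-3D spectra.  Each crosspeak draws a reference amplitude A
#' uniformly in [50, 150] (arbitrary units); the reference intensity is
#' S0(t) = A and the dephased intensity S(t) = A (1 - dephasing(d t)), both
#' with additive Gaussian spectral noise of SD A/snr.  A configured
#' fraction of sites is paired into ambiguous records: the paired sites
#' share a single `ambiguity_group`, and their true couplings are set equal
#' (the mean of the pair), mirroring the observation that overlapped
#' crosspeaks share order parameters.
#'
#' @param profile A [make_profile()] result.
#' @param config The matching [synthetic_config()].
#' @return List of [crosspeak_record()]; the (ambiguity-adjusted) truth is
#'   in `attr(, "truth")` and the seed in `attr(, "seed")`.
#' @export
synth_intensities <- function(profile, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("residue", "d_true") %in% names(profile)))
  set.seed(config$seed)
  truth <- profile
  n <- nrow(truth)
  n_pairs <- floor(config$ambiguous_fraction * n / 2)
  amb_first <- if (n_pairs > 0)
    sort(sample(seq_len(n - 1L), n_pairs)) else integer(0)
  group_of <- rep(NA_character_, n)
  for (i in amb_first) {
    d_shared <- mean(truth$d_true[c(i, i + 1L)])
    truth$d_true[c(i, i + 1L)] <- d_shared
    truth$S_true[c(i, i + 1L)] <- d_shared / rigid_coupling(1.45)
    group_of[c(i, i + 1L)] <- sprintf("amb_%d_%d", truth$residue[i],
                                      truth$residue[i + 1L])
  }
  tvec <- config$dephasing_times
  kinds <- c("DARR", "RFDR", "INADEQUATE")
  records <- list()
  for (i in seq_len(n)) {
    frac <- redor_universal(truth$d_true[i] * tvec)
    for (k in seq_len(config$crosspeaks_per_site)) {
      A <- stats::runif(1, 50, 150)
      sg <- A / config$snr
      records[[length(records) + 1L]] <- crosspeak_record(
        label = sprintf("R%dCA-N#%d", truth$residue[i], k),
        times = tvec,
        S = A * (1 - frac) + stats::rnorm(length(tvec), 0, sg),
        S0 = A + stats::rnorm(length(tvec), 0, sg),
        noise_sigma = sg,
        spectrum_kind = kinds[(k - 1L) %% 3L + 1L],
        site = sprintf("%d.CA-N", truth$residue[i]),
        ambiguity_group = group_of[i])
    }
  }
  attr(records, "truth") <- truth
  attr(records, "seed") <- config$seed
  records
}

# place atom D given A-B-C positions and internal coordinates
# (bond length C-D, angle B-C-D in deg, torsion A-B-C-D in deg)
.nerf_place <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal alpha-helix backbone fixture
#'
#' Builds an ideal alpha-helix backbone (N, CA, C per residue) from
#' standard internal coordinates (N--CA 1.458, CA--C 1.525, C--N 1.329
#' Angstrom; phi = -57, psi = -47, omega = 180 degrees), producing the
#' canonical 1.5 Angstrom rise and ~100 degree twist per residue, aligns
#' the helix axis with z, and optionally writes the coordinates in PDB
#' format.  Also exposes the Calpha-to-N unit bond vectors and distances of
#' the intra-residue (i) and sequential (i+1) nitrogens used by the
#' three-spin validation.
#'
#' @param n_residues Number of residues (>= 5).
#' @param path Optional PDB output path.
#' @return List with `atoms` (data frame: residue, atom, x, y, z),
#'   `ca_n` and `ca_n_next` (per-residue data frames with unit-vector
#'   components `ux, uy, uz` and `dist` in Angstrom), and `path`.
#' @export
synth_helix <- function(n_residues, path = NULL) {
  if (n_residues < 5L) stop("need at least 5 residues for a helix")
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_CNCa <- 121.7; a_NCaC <- 111.2; a_CaCN <- 116.2
  phi <- -57; psi <- -47; omega <- 180
  coords <- matrix(NA_real_, nrow = 3L * n_residues, ncol = 3L)
  atom <- rep(c("N", "CA", "C"), n_residues)
  resno <- rep(seq_len(n_residues), each = 3L)
  # seed the first residue in an arbitrary frame
  coords[1, ] <- c(0, 0, 0)                                  # N1
  coords[2, ] <- c(b_NCa, 0, 0)                              # CA1
  ang <- a_NCaC * pi / 180
  coords[3, ] <- coords[2, ] + b_CaC * c(-cos(ang), sin(ang), 0)  # C1
  for (i in 2:n_residues) {
    r <- 3L * (i - 1L)
    coords[r + 1L, ] <- .nerf_place(coords[r - 2L, ], coords[r - 1L, ],
                                    coords[r, ], b_CN, a_CaCN, psi)
    coords[r + 2L, ] <- .nerf_place(coords[r - 1L, ], coords[r, ],
                                    coords[r + 1L, ], b_NCa, a_CNCa, omega)
    coords[r + 3L, ] <- .nerf_place(coords[r, ], coords[r + 1L, ],
                                    coords[r + 2L, ], b_CaC, a_NCaC, phi)
  }
  # align the helix axis (leading principal component of the CA trace) to +z
  ca <- coords[atom == "CA", ]
  ctr <- colMeans(ca)
  axis <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (axis[3] < 0) axis <- -axis
  z <- c(0, 0, 1)
  v <- pracma::cross(axis, z); s <- sqrt(sum(v^2)); cth <- sum(axis * z)
  R <- if (s < 1e-12) diag(3) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  coords <- sweep(coords, 2, ctr) %*% t(R)
  atoms <- data.frame(residue = resno, atom = atom,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (!is.null(path)) {
    bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                     resno = resno, resid = rep("ALA", length(resno)),
                     elety = atom, chain = rep("A", length(resno)))
  }
  nn <- coords[atom == "N", , drop = FALSE]
  cc <- coords[atom == "CA", , drop = FALSE]
  unitize <- function(v) {
    d <- sqrt(rowSums(v^2))
    data.frame(ux = v[, 1] / d, uy = v[, 2] / d, uz = v[, 3] / d, dist = d)
  }
  ca_n <- cbind(residue = seq_len(n_residues), unitize(nn - cc))
  nxt <- nn[-1, , drop = FALSE] - cc[-n_residues, , drop = FALSE]
  ca_n_next <- cbind(residue = seq_len(n_residues - 1L), unitize(nxt))
  invisible(list(atoms = atoms, ca_n = ca_n, ca_n_next = ca_n_next,
                 path = path))
}

#' Three-spin CN2 cluster from the ideal-helix geometry
#'
#' Builds the validation [spin_cluster()] for an observed Calpha coupled to
#' the amide nitrogens of its own residue and of the next residue, using
#' unit bond vectors taken from the ideal alpha-helix and the typical
#' coupling constants of those two distances (1005 and 200 Hz).
#'
#' @param helix A [synth_helix()] result.
#' @param residue Residue index of the observed Calpha (must have a
#'   successor).
#' @param couplings Length-2 coupling constants, Hz.
#' @return A [spin_cluster()] with two partners.
#' @export
cn2_cluster <- function(helix, residue = NULL, couplings = c(1005, 200)) {
  n <- max(helix$ca_n$residue)
  if (is.null(residue)) residue <- n %/% 2L
  if (residue >= n) stop("'residue' needs a successor in the helix")
  v1 <- unlist(helix$ca_n[helix$ca_n$residue == residue,
                          c("ux", "uy", "uz")])
  v2 <- unlist(helix$ca_n_next[helix$ca_n_next$residue == residue,
                               c("ux", "uy", "uz")])
  spin_cluster(couplings, rbind(v1, v2))
}
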