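#' Crosspeak intensity record
#'
#' Raw per-crosspeak intensities from a pseudo-3D REDOR experiment: the
#' dephased signal S and the reference echo S0 at each dephasing time,
#' together with the per-spectrum RMS noise.
#'
#' @param label Assignment string, e.g. `"A9CA-CB"`.
#' @param times Dephasing times in seconds, strictly increasing.
#' @param S,S0 Intensities (arbitrary units), same length as `times`.
#' @param noise_sigma RMS spectral noise, same intensity units (> 0).
#' @param spectrum_kind One of `"DARR"`, `"RFDR"`, `"INADEQUATE"`.
#' @param site Identifier of the underlying C--N bond (shared by replicate
#'   crosspeaks of one site), e.g. `"9.CA-N"`; `NA` if unknown.
#' @param ambiguity_group Optional identifier linking overlapped crosspeaks
#'   whose assignment is ambiguous between two sites.
#' @return A `crosspeak_record`.
#' @export
crosspeak_record <- function(label, times, S, S0, noise_sigma,
                             spectrum_kind = c("DARR", "RFDR", "INADEQUATE"),
                             site = NA_character_,
                             ambiguity_group = NA_character_) {
  spectrum_kind <- match.arg(spectrum_kind)
  times <- as.numeric(times)
  if (length(times) < 1L) stop("record needs at least one time point")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (length(S) != length(times) || length(S0) != length(times))
    stop("'S' and 'S0' must match 'times' in length")
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma <= 0)
    stop("'noise_sigma' must be a single positive value")
  structure(list(label = as.character(label), spectrum_kind = spectrum_kind,
                 times = times, S = as.numeric(S), S0 = as.numeric(S0),
                 noise_sigma = noise_sigma, site = as.character(site),
                 ambiguity_group = as.character(ambiguity_group)),
            class = "crosspeak_record")
}

#' Assemble a REDOR buildup curve from one crosspeak
#'
#' Converts intensities to dephasing fractions \eqn{\Delta S/S_0 = 1 -
#' S/S_0} with per-point uncertainties by first-order error propagation of
#' the spectral noise through the ratio:
#' \deqn{\sigma_f = \sqrt{(\sigma/S_0)^2 + (S\,\sigma/S_0^2)^2}.}
#' Points whose reference intensity falls below `snr_floor` times the noise
#' are dropped (they carry no usable ratio) with a message.
#'
#' @param record A [crosspeak_record()].
#' @param snr_floor Minimum S0/noise ratio for a point to be retained.
#' @return A `buildup_curve`: data frame with columns `time`, `fraction`,
#'   `sigma`; contributing labels in `attr(, "source_labels")`.
#' @export
assemble_buildup <- function(record, snr_floor = 3) {
  stopifnot(inherits(record, "crosspeak_record"))
  keep <- record$S0 / record$noise_sigma >= snr_floor & record$S0 > 0
  if (any(!keep))
    message(sprintf("%s: dropped %d point(s) below the S0 SNR floor (%.1f)",
                    record$label, sum(!keep), snr_floor))
  if (sum(keep) < 3L)
    stop(sprintf("insufficient data for '%s': %d usable point(s), need >= 3",
                 record$label, sum(keep)))
  S <- record$S[keep]; S0 <- record$S0[keep]; sg <- record$noise_sigma
  curve <- data.frame(
    time = record$times[keep],
    fraction = 1 - S / S0,
    sigma = sqrt((sg / S0)^2 + (S * sg / S0^2)^2)
  )
  attr(curve, "source_labels") <- record$label
  class(curve) <- c("buildup_curve", "data.frame")
  curve
}

#' Fit an effective dipolar coupling to a buildup curve
#'
#' Minimizes \eqn{\chi^2(d) = \sum_i (f_i - \Delta S/S_0(d t_i))^2 /
#' \sigma_i^2} over the universal REDOR curve by a coarse grid scan followed
#' by local refinement.  The uncertainty is the symmetric-ized
#' \eqn{\Delta\chi^2 = 1} profile interval about the minimum.  Flat valleys
#' are broken towards the smallest coupling within 0.01 chi-square units of
#' the minimum.
#'
#' @param curve A [assemble_buildup()] result (or any data frame with
#'   `time`, `fraction`, `sigma`).
#' @param d_max Upper edge of the coupling search grid, Hz.
#' @param d_step Coarse grid spacing, Hz.
#' @param fraction_cap Optional cap: drop points with fraction above it
#'   (e.g. 0.6 to restrict the fit to the initial rise); `NULL` keeps all.
#' @return A `coupling_fit`: list with `d_hat`, `d_sigma` (Hz),
#'   `chi2`, `chi2_reduced`, `n_points`, `fit_range_max_fraction`, and a
#'   `boundary` flag set when the minimum sits at the grid edge.
#' @export
fit_coupling <- function(curve, d_max = 1200, d_step = 2,
                         fraction_cap = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time", "fraction", "sigma") %in% names(curve)))
  if (!is.null(fraction_cap)) curve <- curve[curve$fraction <= fraction_cap, ]
  if (nrow(curve) < 3L) stop("insufficient data: need >= 3 points to fit")
  if (any(curve$sigma <= 0)) stop("point uncertainties must be positive")
  tt <- curve$time; ff <- curve$fraction; ss <- curve$sigma
  chisq <- function(d) {
    vapply(d, function(di)
      sum((ff - redor_universal(di * tt))^2 / ss^2), numeric(1))
  }
  d_grid <- seq(0, d_max, by = d_step)
  c_grid <- chisq(d_grid)
  cmin <- min(c_grid)
  # tie-break: smallest d within 0.01 chi-square units of the minimum
  i <- which(c_grid <= cmin + 0.01)[1L]
  lo <- max(d_grid[i] - d_step, 0); hi <- min(d_grid[i] + d_step, d_max)
  opt <- stats::optimize(chisq, c(lo, hi), tol = 1e-4)
  d_hat <- opt$minimum; chi2 <- opt$objective
  if (chisq(0) <= chi2 + 1e-12) { d_hat <- 0; chi2 <- chisq(0) }
  boundary <- d_hat >= d_max - d_step
  if (boundary)
    warning("chi-square minimum at the coupling grid boundary; ",
            "increase 'd_max'")
  # Delta-chi2 = 1 profile interval, symmetric-ized
  up <- function(d) chisq(d) - (chi2 + 1)
  upper <- if (up(d_max * 1.5) > 0)
    stats::uniroot(up, c(d_hat, d_max * 1.5), tol = 1e-6)$root else d_max * 1.5
  lower <- if (d_hat > 0 && up(0) > 0)
    stats::uniroot(up, c(0, d_hat), tol = 1e-6)$root else 0
  d_sigma <- if (d_hat > 0 && lower > 0) (upper - lower) / 2 else upper - d_hat
  structure(list(d_hat = d_hat, d_sigma = d_sigma, chi2 = chi2,
                 chi2_reduced = chi2 / max(nrow(curve) - 1L, 1L),
                 n_points = nrow(curve),
                 fit_range_max_fraction = max(ff),
                 boundary = boundary),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("coupling fit: d = %.1f +/- %.1f Hz (reduced chi2 %.2f, n = %d)\n",
              x$d_hat, x$d_sigma, x$chi2_reduced, x$n_points))
  if (isTRUE(x$ambiguous)) cat("  [ambiguous crosspeaks fit jointly]\n")
  invisible(x)
}

#' Joint coupling fit over all crosspeaks of one site
#'
#' Multiple crosspeaks reporting on the same C--N bond are combined either by
#' pooling all (time, fraction, sigma) points into a single joint chi-square
#' fit (default) or by averaging the per-crosspeak couplings weighted by
#' their inverse variances.  Records linked by an `ambiguity_group` (one
#' crosspeak overlapping two assignments) are fitted to a single dephasing
#' curve and the result is flagged `ambiguous`.
#'
#' @param records List of [crosspeak_record()] for one bond.
#' @param method `"pool"` (joint fit) or `"average"` (inverse-variance mean
#'   of per-crosspeak fits).
#' @param snr_floor Passed to [assemble_buildup()].
#' @param ... Passed to [fit_coupling()].
#' @return A `coupling_fit` with `source_labels` and `ambiguous` fields.
#' @export
combine_site <- function(records, method = c("pool", "average"),
                         snr_floor = 3, ...) {
  method <- match.arg(method)
  if (length(records) == 0L) stop("empty record list")
  stopifnot(all(vapply(records, inherits, logical(1), "crosspeak_record")))
  sites <- unique(stats::na.omit(vapply(records, `[[`, character(1), "site")))
  groups <- unique(stats::na.omit(vapply(records, `[[`, character(1),
                                         "ambiguity_group")))
  ambiguous <- length(groups) > 0L
  if (length(sites) > 1L && !ambiguous)
    stop("conflicting site assignments: ",
         paste(vapply(records, `[[`, character(1), "label"), collapse = ", "))
  curves <- lapply(records, assemble_buildup, snr_floor = snr_floor)
  fit <- if (method == "pool") {
    pooled <- do.call(rbind, lapply(curves, as.data.frame))
    fit_coupling(pooled, ...)
  } else {
    fits <- lapply(curves, fit_coupling, ...)
    w <- vapply(fits, function(f) 1 / f$d_sigma^2, numeric(1))
    d <- vapply(fits, `[[`, numeric(1), "d_hat")
    n <- sum(vapply(fits, `[[`, integer(1), "n_points"))
    structure(list(d_hat = sum(w * d) / sum(w),
                   d_sigma = 1 / sqrt(sum(w)),
                   chi2 = sum(vapply(fits, `[[`, numeric(1), "chi2")),
                   chi2_reduced = NA_real_, n_points = n,
                   fit_range_max_fraction =
                     max(vapply(fits, `[[`, numeric(1),
                                "fit_range_max_fraction")),
                   boundary = any(vapply(fits, `[[`, logical(1), "boundary"))),
              class = "coupling_fit")
  }
  fit$source_labels <- vapply(records, `[[`, character(1), "label")
  fit$ambiguous <- ambiguous
  fit
}
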