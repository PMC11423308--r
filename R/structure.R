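#' Load backbone N/CA coordinates from a PDB file
#'
#' Reads a coordinate file and returns, per residue, the amide nitrogen and
#' alpha-carbon positions needed for Calpha--N bond-vector geometry.
#' Residues missing either atom are skipped with a warning.
#'
#' @param path Path to a PDB-format file.
#' @param chain Optional chain identifier; default uses all chains.
#' @return Data frame with columns `residue`, `chain`, `n_x`, `n_y`, `n_z`,
#'   `ca_x`, `ca_y`, `ca_z`, ordered by residue number.
#' @export
load_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  a <- a[a$elety %in% c("N", "CA"), ]
  if (nrow(a) == 0L) stop("no usable N/CA atoms in ", path)
  key <- paste(a$chain, a$resno)
  rows <- lapply(unique(key), function(k) {
    sub <- a[key == k, ]
    n <- sub[sub$elety == "N", ][1, ]
    ca <- sub[sub$elety == "CA", ][1, ]
    if (nrow(sub[sub$elety == "N", ]) == 0L ||
        nrow(sub[sub$elety == "CA", ]) == 0L) {
      warning("residue ", k, " missing N or CA; skipped")
      return(NULL)
    }
    data.frame(residue = ca$resno, chain = ca$chain,
               n_x = n$x, n_y = n$y, n_z = n$z,
               ca_x = ca$x, ca_y = ca$y, ca_z = ca$z)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no residues with both N and CA")
  out[order(out$residue), , drop = FALSE]
}

#' Bond-vector angles to the filament axis and predicted order parameters
#'
#' For each residue, computes the angle between the Calpha-to-N bond vector
#' and a filament axis, and the order parameter that a fast uniaxial
#' rotation of the whole assembly about that axis would impose on the bond:
#' \eqn{|S| = |P_2(\cos\theta)|}.  The axis defaults to the z axis, the
#' fiber-symmetry convention of deposited filament structures.
#'
#' @param residues Data frame from [load_structure()].
#' @param axis Length-3 axis vector (need not be normalized, must be
#'   non-zero).
#' @return A `bond_geometry` data frame with columns `residue`,
#'   `angle_deg` and `predicted_S_abs`.
#' @export
bond_axis_angles <- function(residues, axis = c(0, 0, 1)) {
  stopifnot(all(c("residue", "n_x", "ca_x") %in% names(residues)))
  nr <- sqrt(sum(axis^2))
  if (nr == 0) stop("axis vector must be non-zero")
  a <- axis / nr
  v <- cbind(residues$n_x - residues$ca_x,
             residues$n_y - residues$ca_y,
             residues$n_z - residues$ca_z)
  v <- v / sqrt(rowSums(v^2))
  ct <- pmin(pmax(v %*% a, -1), 1)
  out <- data.frame(residue = residues$residue,
                    angle_deg = as.numeric(acos(ct)) * 180 / pi,
                    predicted_S_abs = abs((3 * as.numeric(ct)^2 - 1) / 2))
  class(out) <- c("bond_geometry", "data.frame")
  out
}

#' Compare axial-rotation predictions with experimental order parameters
#'
#' Joins predicted |S| values (from [bond_axis_angles()]) with experimental
#' per-residue order parameters and reports the root-mean-square
#' discrepancy and the spread (max - min) of each profile.  A fast global
#' rotation about the filament axis predicts large residue-to-residue
#' oscillations in |S|; a uniform experimental profile with a much smaller
#' spread is inconsistent with that motion.  The function reports the
#' statistics only; it makes no decision.
#'
#' @param geometries A [bond_axis_angles()] result.
#' @param experimental Data frame with columns `residue` and `S`
#'   (a [build_site_table()] result works directly).
#' @return List with `pairs` (residue, angle_deg, predicted_S_abs,
#'   experimental_S), `rms_discrepancy`, `predicted_range`,
#'   `experimental_range`.
#' @export
compare_to_experiment <- function(geometries, experimental) {
  stopifnot(all(c("residue", "predicted_S_abs") %in% names(geometries)),
            all(c("residue", "S") %in% names(experimental)))
  m <- merge(as.data.frame(geometries),
             data.frame(residue = experimental$residue,
                        experimental_S = abs(experimental$S)),
             by = "residue")
  if (nrow(m) == 0L) stop("no residues common to predictions and experiment")
  list(pairs = m[order(m$residue), ],
       rms_discrepancy = sqrt(mean((m$predicted_S_abs - m$experimental_S)^2)),
       predicted_range = diff(range(m$predicted_S_abs)),
       experimental_range = diff(range(m$experimental_S)))
}
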