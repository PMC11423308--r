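test_that("the synthetic helix has canonical backbone geometry", {
  h <- synth_helix(50)
  expect_equal(nrow(h$ca_n), 50L)
  # intra-residue CA-N bond length
  expect_true(all(abs(h$ca_n$dist - 1.45) < 0.05))
  # sequential CA-N(i+1) distance gives a passive coupling near 200 Hz
  r_next <- mean(h$ca_n_next$dist)
  expect_equal(r_next, 2.45, tolerance = 0.05)
  expect_true(all(rigid_coupling(h$ca_n_next$dist) > 180 &
                    rigid_coupling(h$ca_n_next$dist) < 235))
  # helix axis aligned with z
  ca <- h$atoms[h$atoms$atom == "CA", c("x", "y", "z")]
  ax <- svd(sweep(as.matrix(ca), 2, colMeans(ca)))$v[, 1]
  expect_lt(acos(abs(ax[3])) * 180 / pi, 2)
  # canonical rise per residue
  expect_equal(mean(diff(ca$z)), 1.5, tolerance = 0.1)
  expect_error(synth_helix(4), "at least 5")
})

test_that("PDB round trip preserves the residue set", {
  path <- tempfile(fileext = ".pdb")
  h <- synth_helix(50, path = path)
  res <- load_structure(path)
  expect_equal(nrow(res), 50L)
  expect_equal(res$residue, 1:50)
  expect_equal(res$ca_x, h$atoms$x[h$atoms$atom == "CA"], tolerance = 1e-3)

  # drop one N atom: that residue disappears with a warning
  lines <- readLines(path)
  drop <- which(startsWith(lines, "ATOM") &
                  trimws(substr(lines, 13, 16)) == "N" &
                  trimws(substr(lines, 23, 26)) == "25")[1]
  writeLines(lines[-drop], path)
  expect_warning(res2 <- load_structure(path), "missing N or CA")
  expect_equal(nrow(res2), 49L)
  expect_false(25 %in% res2$residue)
})

test_that("bond-axis angles map to rank-2 order parameters", {
  res <- data.frame(residue = 1:3, chain = "A",
                    n_x = c(0, 1, sin(54.7356 * pi / 180)),
                    n_y = 0,
                    n_z = c(1, 0, cos(54.7356 * pi / 180)),
                    ca_x = 0, ca_y = 0, ca_z = 0)
  geo <- bond_axis_angles(res)
  expect_equal(geo$angle_deg, c(0, 90, 54.7356), tolerance = 1e-4)
  expect_equal(geo$predicted_S_abs[1], 1)
  expect_equal(geo$predicted_S_abs[2], 0.5)
  expect_lt(geo$predicted_S_abs[3], 1e-6)
  expect_error(bond_axis_angles(res, axis = c(0, 0, 0)), "non-zero")

  # inverting a bond vector leaves the prediction unchanged (rank-2)
  flipped <- res
  flipped[, c("n_x", "n_y", "n_z")] <- -flipped[, c("n_x", "n_y", "n_z")]
  expect_equal(bond_axis_angles(flipped)$predicted_S_abs,
               geo$predicted_S_abs, tolerance = 1e-12)
})

test_that("axial rotation predicts large oscillations an ideal helix cannot hide", {
  path <- tempfile(fileext = ".pdb")
  synth_helix(50, path = path)
  res <- load_structure(path)

  # aligned helix: residues are related by rotation about the axis, so the
  # residual oscillation is tiny but still carries the 3.6-residue repeat
  geo0 <- bond_axis_angles(res)
  x <- geo0$predicted_S_abs - mean(geo0$predicted_S_abs)
  period <- length(x) / which.max(Mod(fft(x))[2:(length(x) %/% 2)])
  expect_gt(period, 3.2)
  expect_lt(period, 4.1)
  expect_lt(diff(range(geo0$predicted_S_abs)), 0.05)

  # helix tilted ~20 deg from the filament axis (as the coat-protein helix
  # is in the virion): the bond-to-axis angle sweeps a wide cone every turn
  tilt <- 20 * pi / 180
  geo <- bond_axis_angles(res, axis = c(sin(tilt), 0, cos(tilt)))
  xa <- geo$angle_deg - mean(geo$angle_deg)
  period_a <- length(xa) / which.max(Mod(fft(xa))[2:(length(xa) %/% 2)])
  expect_gt(period_a, 3.2)
  expect_lt(period_a, 4.1)

  uniform <- data.frame(residue = 1:50, S = 0.66)
  cmp <- compare_to_experiment(geo, uniform)
  expect_gt(cmp$predicted_range, 0.5)
  expect_lt(cmp$experimental_range, 0.05)
  expect_equal(nrow(cmp$pairs), 50L)

  # perfect agreement gives zero discrepancy
  self <- compare_to_experiment(geo, data.frame(residue = geo$residue,
                                                S = geo$predicted_S_abs))
  expect_equal(self$rms_discrepancy, 0)

  # single overlapping residue still produces one pair
  one <- compare_to_experiment(geo, data.frame(residue = 25, S = 0.66))
  expect_equal(nrow(one$pairs), 1L)
  expect_error(compare_to_experiment(geo, data.frame(residue = 99, S = 1)),
               "common")
})
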