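test_that("buildup assembly converts intensities to fractions with propagated errors", {
  tt <- c(6, 8, 16, 24) * 71.4e-6
  r <- crosspeak_record("A9CA-CB", tt, S = rep(60, 4), S0 = rep(100, 4),
                        noise_sigma = 5)
  b <- assemble_buildup(r)
  expect_equal(b$fraction, rep(0.4, 4))
  # hand-evaluated first-order propagation through 1 - S/S0
  expect_equal(b$sigma, rep(sqrt((5 / 100)^2 + (60 * 5 / 100^2)^2), 4),
               tolerance = 1e-12)

  same <- crosspeak_record("x", tt, S = rep(80, 4), S0 = rep(80, 4),
                           noise_sigma = 1)
  expect_equal(assemble_buildup(same)$fraction, rep(0, 4))
  gone <- crosspeak_record("x", tt, S = rep(0, 4), S0 = rep(50, 4),
                           noise_sigma = 1)
  expect_equal(assemble_buildup(gone)$fraction, rep(1, 4))
})

test_that("low-SNR points are dropped and too-few points is an error", {
  tt <- c(2, 4, 6, 8) * 71.4e-6
  r <- crosspeak_record("weak", tt, S = c(50, 40, 30, 1),
                        S0 = c(100, 90, 80, 2), noise_sigma = 5)
  expect_message(b <- assemble_buildup(r), "dropped 1")
  expect_equal(nrow(b), 3L)
  r2 <- crosspeak_record("gone", tt, S = rep(1, 4), S0 = rep(2, 4),
                         noise_sigma = 5)
  expect_error(suppressMessages(assemble_buildup(r2)), "insufficient")
})

test_that("record validation enforces time ordering and noise positivity", {
  expect_error(crosspeak_record("x", c(2, 1) * 1e-4, c(1, 1), c(2, 2), 1),
               "strictly increasing")
  expect_error(crosspeak_record("x", c(1, 2) * 1e-4, c(1, 1), c(2, 2), 0),
               "positive")
  expect_error(crosspeak_record("x", c(1, 2) * 1e-4, c(1, 1, 1), c(2, 2), 1),
               "length")
})

test_that("fitting a noiseless universal curve recovers the coupling", {
  tt <- seq(2, 16, by = 2) * 71.4e-6
  curve <- data.frame(time = tt, fraction = redor_universal(663 * tt),
                      sigma = 0.01)
  fit <- fit_coupling(curve)
  expect_equal(fit$d_hat, 663, tolerance = 1 / 663)
  expect_lt(fit$chi2_reduced, 1e-6)
  expect_gt(fit$d_sigma, 0)

  flat <- curve; flat$fraction <- 0
  expect_identical(fit_coupling(flat)$d_hat, 0)
})

test_that("fit is invariant to a common intensity rescaling", {
  set.seed(11)
  r <- noisy_record(600)
  r2 <- r
  r2$S <- r$S * 7.3; r2$S0 <- r$S0 * 7.3; r2$noise_sigma <- r$noise_sigma * 7.3
  f1 <- fit_coupling(assemble_buildup(r))
  f2 <- fit_coupling(assemble_buildup(r2))
  expect_equal(f1$d_hat, f2$d_hat, tolerance = 1e-6)
  expect_equal(f1$d_sigma, f2$d_sigma, tolerance = 1e-6)
})

test_that("a boundary minimum is flagged", {
  tt <- seq(2, 8, by = 2) * 71.4e-6
  curve <- data.frame(time = tt, fraction = redor_universal(1150 * tt),
                      sigma = 0.01)
  expect_warning(fit <- fit_coupling(curve, d_max = 800), "boundary")
  expect_true(fit$boundary)
})

test_that("parameter recovery at study-like noise meets the 10 percent median error", {
  set.seed(42)
  d_true <- runif(100, 0.15, 1.0) * rigid_coupling(1.45)
  err <- vapply(d_true, function(d) {
    recs <- replicate(3, noisy_record(d), simplify = FALSE)
    abs(combine_site(recs)$d_hat - d) / d
  }, numeric(1))
  expect_lte(median(err), 0.10)
})

test_that("pooling replicate crosspeaks shrinks the coupling uncertainty like 1/sqrt(n)", {
  set.seed(5)
  ratios <- replicate(8, {
    one <- combine_site(list(noisy_record(663)))
    four <- combine_site(replicate(4, noisy_record(663), simplify = FALSE))
    four$d_sigma / one$d_sigma
  })
  expect_equal(mean(ratios), 0.5, tolerance = 0.2)
})

test_that("site combination honours assignments and ambiguity groups", {
  r <- noiseless_record(600)
  expect_equal(combine_site(list(r, r))$d_hat,
               fit_coupling(assemble_buildup(r))$d_hat, tolerance = 1e-6)

  other <- noiseless_record(600, site = "2.CA-N", label = "Y2CA-CB")
  expect_error(combine_site(list(r, other)), "conflicting")
  expect_error(combine_site(list()), "empty")

  # ambiguous pair with equal true coupling: joint fit recovers it
  set.seed(9)
  a <- noisy_record(500, site = "9.CA-N", label = "A9CA-CB",
                    ambiguity_group = "amb_9_10")
  b <- noisy_record(500, site = "10.CA-N", label = "A10CA-CB",
                    ambiguity_group = "amb_9_10")
  joint <- combine_site(list(a, b))
  expect_true(joint$ambiguous)
  expect_lt(abs(joint$d_hat - 500), 2 * joint$d_sigma + 1e-9)
})

test_that("averaging mode weights per-crosspeak fits by inverse variance", {
  set.seed(13)
  recs <- replicate(3, noisy_record(700), simplify = FALSE)
  avg <- combine_site(recs, method = "average")
  fits <- lapply(recs, function(r) fit_coupling(assemble_buildup(r)))
  w <- vapply(fits, function(f) 1 / f$d_sigma^2, numeric(1))
  d <- vapply(fits, `[[`, numeric(1), "d_hat")
  expect_equal(avg$d_hat, sum(w * d) / sum(w), tolerance = 1e-9)
  expect_lt(avg$d_sigma, min(vapply(fits, `[[`, numeric(1), "d_sigma")))
})
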