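test_that("two-point replicate pairs give the closed-form bin SD", {
  # every pair {m - d, m + d}: sample SD is d * sqrt(2); the unbiased curve
  # divides by c4(2) = sqrt(2/pi)
  d <- 0.7
  ms <- seq(10, 150, by = 10)
  treated <- lapply(ms, function(m) list(c(m - d, m + d), c(2 * m - d, 2 * m + d)))
  ctrl <- cbind(ms * 3 - d, ms * 3 + d)
  rs <- make_repset(treated, ctrl)
  raw <- build_noise_curve(rs, n_bins = 5, unbiased = FALSE)
  expect_equal(raw$bin_sd, rep(d * sqrt(2), 5), tolerance = 1e-12)
  unb <- build_noise_curve(rs, n_bins = 5, unbiased = TRUE)
  expect_equal(unb$bin_sd, rep(d * sqrt(2) / sqrt(2 / pi), 5), tolerance = 1e-12)
  expect_equal(sum(raw$n_pairs_per_bin), length(ms) * 3L)
})

test_that("noise curve is invariant to replicate and row order", {
  gen <- generate_replicate_expression(synth_expression_config(n_genes = 80, seed = 4))
  v <- gen$data$values
  base <- build_noise_curve(gen$data)
  perm_rep <- replicate_set(v[, , c(3, 1, 2)], gen$data$control_values)
  g <- sample(dim(v)[1L]); s <- sample(dim(v)[2L])
  perm_rows <- replicate_set(v[g, s, ], gen$data$control_values[g, ])
  for (other in list(perm_rep, perm_rows)) {
    cv <- build_noise_curve(other)
    expect_equal(cv$bin_sd, base$bin_sd)
    expect_equal(cv$bin_mean_expression, base$bin_mean_expression)
  }
})

test_that("curve estimation fails loudly without usable replicates", {
  v <- array(NA_real_, c(2, 2, 3))
  v[1, 1, 1] <- 5  # single replicate only
  rs <- replicate_set(v, matrix(NA_real_, 2, 4))
  expect_error(build_noise_curve(rs), ">= 2 replicates")
})

test_that("interpolate_sd follows nodes, midpoints and extrapolation rules", {
  cu <- make_curve(c(10, 20, 40), c(2, 6, 3))
  expect_equal(interpolate_sd(cu, c(10, 20, 40)), c(2, 6, 3))
  expect_equal(interpolate_sd(cu, 15), 4)          # linear midpoint
  expect_equal(interpolate_sd(cu, 30), 4.5)
  expect_equal(interpolate_sd(cu, -100), 2)        # constant below range
  expect_equal(interpolate_sd(cu, 1e6), 3)         # constant above range
  expect_error(interpolate_sd(cu, NaN), "non-finite")
  expect_error(interpolate_sd(cu, Inf), "non-finite")
})

test_that("outlier removal traces the iteration the way a hand computation does", {
  cu <- flat_curve(1)
  rs <- make_repset(list(list(c(10, 10.1, 9.9), c(10, 10.1, 50))),
                    matrix(c(10, 10, 10, 10), 1))
  res <- remove_outliers(rs, cu)
  # {10, 10.1, 9.9}: all within 3 SD, nothing flagged
  expect_false(any(res$report$flags[1, 1, ]))
  # {10, 10.1, 50}: worst value removed first, survivors then consistent
  expect_identical(res$report$flags[1, 2, ], c(FALSE, FALSE, TRUE))
  expect_equal(sort(res$data$values[1, 2, 1:2]), c(10, 10.1))
  expect_equal(nrow(res$report$discarded_pairs), 0L)
})

test_that("pairs left with fewer than two survivors are discarded", {
  cu <- flat_curve(1)
  rs <- make_repset(list(list(c(10, 60))), matrix(c(10, 10, 10), 1))
  res <- remove_outliers(rs, cu)
  expect_equal(nrow(res$report$discarded_pairs), 1L)
  expect_true(all(is.na(res$data$values[1, 1, ])))
})

test_that("outlier removal is idempotent", {
  gen <- generate_replicate_expression(synth_expression_config(n_genes = 400, seed = 17))
  curve <- build_noise_curve(gen$data)
  pass1 <- remove_outliers(gen$data, curve)
  pass2 <- remove_outliers(pass1$data, curve)
  expect_equal(sum(pass2$report$flags), 0L)
  expect_equal(sum(pass2$report$control_flags), 0L)
})

test_that("constant noise integrates to an affine saturation curve", {
  cu <- flat_curve(2.5)
  sat <- build_saturation_curve(cu, assumed_true_sd = 2.5)
  slopes <- diff(sat$F_values) / diff(sat$g_grid)
  expect_true(all(abs(slopes - 1) < 1e-9))  # unit slope at matching true SD
})

test_that("linear noise curve recovers the logarithmic closed form", {
  # sd_obs(F) = c * (1 - F/Fmax)  =>  g(F) = -(c_true/c) * Fmax * log(1 - F/Fmax) + const
  fmax <- 1000; cc <- 8
  fs <- seq(50, 900, length.out = 12)
  cu <- make_curve(fs, cc * (1 - fs / fmax))
  sat <- build_saturation_curve(cu, assumed_true_sd = cc, n_grid = 8192)
  inside <- sat$F_values >= 100 & sat$F_values <= 850
  g_hat <- sat$g_grid[inside]
  g_true <- -fmax * log(1 - sat$F_values[inside] / fmax)
  fit <- lm(g_hat ~ g_true)
  rel_dev <- abs(residuals(fit)) / diff(range(g_hat))
  expect_lt(max(rel_dev), 0.01)
})

test_that("zero interpolated SD is rejected during integration", {
  cu <- make_curve(c(10, 20), c(1, 0))
  cu$bin_sd <- c(1, 0)
  expect_error(build_saturation_curve(cu), "non-positive|degenerate")
})

test_that("linearization is the identity under an identity curve and inverts F", {
  cu <- flat_curve(1)
  sat <- build_saturation_curve(cu, assumed_true_sd = 1)
  gen <- generate_replicate_expression(synth_expression_config(
    n_genes = 30, signal_range = c(50, 900),
    saturation = list(type = "identity"), outlier_rate = 0, seed = 2))
  lin <- linearize(gen$data, sat)
  expect_equal(lin$values, gen$data$values, tolerance = 1e-9)

  # round trip F(F^-1(v)) = v within interpolation tolerance
  gen2 <- generate_replicate_expression(synth_expression_config(n_genes = 200, seed = 3))
  curve <- build_noise_curve(gen2$data)
  sat2 <- build_saturation_curve(curve)
  v <- as.vector(gen2$data$values)
  v <- v[v > min(sat2$F_values) & v < max(sat2$F_values)]
  expect_equal(sat_apply(sat2, sat_invert(sat2, v)), v, tolerance = 1e-6)

  # order preservation
  x <- sort(runif(100, min(sat2$F_values), max(sat2$F_values)))
  expect_true(all(diff(sat_invert(sat2, x)) >= 0))
})

test_that("curves serialize to two-column TSVs", {
  gen <- generate_replicate_expression(synth_expression_config(n_genes = 100, seed = 8))
  curve <- build_noise_curve(gen$data)
  tdir <- withr::local_tempdir()
  write_curve_tsv(curve, file.path(tdir, "nc.tsv"))
  back <- read.delim(file.path(tdir, "nc.tsv"))
  expect_equal(back$sd, curve$bin_sd)
  sat <- build_saturation_curve(curve)
  write_curve_tsv(sat, file.path(tdir, "sat.tsv"))
  back2 <- read.delim(file.path(tdir, "sat.tsv"))
  expect_equal(back2$g, sat$g_grid)
})
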