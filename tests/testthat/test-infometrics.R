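test_that("entropy matches direct evaluation and degenerate cases", {
  expect_equal(shannon_entropy(rep(c(TRUE, FALSE), c(13, 13))), 1)
  expect_equal(shannon_entropy(rep(TRUE, 9)), 0)
  expect_equal(shannon_entropy(rep(c(TRUE, FALSE), c(2, 6))),
               entropy_oracle(c(2, 6)), tolerance = 1e-15)
  expect_equal(shannon_entropy(rep(c(TRUE, FALSE), c(2, 6))), 0.8112781245,
               tolerance = 1e-9)
  expect_error(shannon_entropy(logical(0)), "empty")
  expect_error(shannon_entropy(c(TRUE, NA)), "NA")
})

test_that("joint entropy matches the brute-force table evaluation", {
  p <- vectors_from_table(10, 3, 3, 10)
  expect_equal(joint_entropy(p$x, p$y), entropy_oracle(c(10, 3, 3, 10)),
               tolerance = 1e-14)
  x <- rep(c(TRUE, FALSE), c(5, 7))
  expect_equal(joint_entropy(x, x), shannon_entropy(x))
  b <- vectors_from_table(1, 1, 1, 1)
  expect_equal(joint_entropy(b$x, b$y), 2)
  expect_error(joint_entropy(x, x[-1]), "length")
})

test_that("mutual information behaves on canonical pairs", {
  x <- rep(c(TRUE, FALSE), 13)
  expect_equal(mutual_information(x, !x), 1)      # complement carries 1 bit
  ind <- vectors_from_table(1, 1, 1, 1)
  expect_equal(mutual_information(ind$x, ind$y), 0)
})

test_that("MI symmetry, complement invariance and entropy bounds hold", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:26, 1)
    x <- runif(n) < runif(1, 0.1, 0.9)
    y <- runif(n) < runif(1, 0.1, 0.9)
    i_xy <- mutual_information(x, y)
    expect_identical(i_xy, mutual_information(y, x))
    expect_equal(i_xy, mutual_information(x, !y), tolerance = 1e-12)
    expect_equal(i_xy, mutual_information(!x, y), tolerance = 1e-12)
    expect_gte(i_xy, 0)
    expect_lte(i_xy, min(shannon_entropy(x), shannon_entropy(y)) + 1e-12)
    expect_lte(joint_entropy(x, y),
               shannon_entropy(x) + shannon_entropy(y) + 1e-12)
  }
})

test_that("permutation p-values hit their boundary cases", {
  x <- rep(c(TRUE, FALSE), c(13, 13))
  res <- permutation_pvalue(x, x, n_perm = 999, seed = 1)
  expect_equal(res$mi, 1)
  expect_equal(res$p_value, 1 / 1000)     # observed MI maximal, add-one floor
  expect_equal(res$pearson, 1)

  const <- rep(TRUE, 26)
  res2 <- permutation_pvalue(const, x, n_perm = 200, seed = 1)
  expect_equal(res2$mi, 0)
  expect_equal(res2$p_value, 1)
  expect_true(is.na(res2$pearson))
  expect_error(permutation_pvalue(x, x, n_perm = 50), ">= 100")
})

test_that("mi_result fields satisfy their invariants on random pairs", {
  set.seed(7)
  for (i in 1:25) {
    x <- runif(20) < 0.5; y <- runif(20) < 0.5
    r <- permutation_pvalue(x, y, n_perm = 199, seed = i)
    expect_equal(r$mi, max(r$h_x + r$h_y - r$h_joint, 0), tolerance = 1e-12)
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("pairwise screen ranks planted dependent pairs above decoys", {
  tr <- generate_translation_dataset(synth_translation_config(
    n_genesets = 20, human_label_noise = 0, frac_anticorrelated = 0.5,
    nes_noise_sd = 0.05, rat_activation_rate = 0.3,
    human_activation_rate = 0.3, seed = 44))
  planted_rat <- tr$rat_activation$on
  planted_hum <- tr$truth$labels
  set.seed(1)
  decoy_rat <- matrix(runif(380 * 52) < 0.3, 380, 52,
                      dimnames = list(sprintf("D%03d", 1:380),
                                      colnames(planted_rat)))
  a <- activation_matrix(rbind(planted_rat, decoy_rat), "gene set", 0.25)
  b <- activation_matrix(rbind(planted_hum, decoy_rat[, sample(52)]),
                         "gene set", 0.25)
  sc <- pairwise_mi_screen(a, b, n_perm = 200, seed = 9, n_null = 20)
  top5 <- sc$table$id_a[seq_len(ceiling(0.05 * nrow(sc$table)))]
  expect_gte(mean(grepl("^GS", top5)), 0.9)
  # anticorrelated planted pairs score as well as correlated ones
  anti_ids <- rownames(planted_rat)[tr$truth$anticorrelated]
  mi_anti <- sc$table$mi_bits[sc$table$id_a %in% anti_ids]
  mi_corr <- sc$table$mi_bits[grepl("^GS", sc$table$id_a) &
                              !(sc$table$id_a %in% anti_ids)]
  expect_gt(mean(mi_anti), mean(mi_corr) - 0.1)
  expect_true(all(sc$table$pearson[sc$table$id_a %in% anti_ids] < 0))
})

test_that("identical matrices under the identity map attain the entropy bound", {
  set.seed(3)
  on <- matrix(runif(10 * 12) < 0.5, 10, 12,
               dimnames = list(sprintf("S%02d", 1:10), NULL))
  a <- activation_matrix(on, "gene set", 0.25)
  sc <- pairwise_mi_screen(a, a, n_perm = 150, seed = 2, n_null = 10)
  h <- apply(on, 1L, shannon_entropy)
  got <- sc$table$mi_bits[match(sprintf("S%02d", 1:10), sc$table$id_a)]
  expect_equal(got, unname(h), tolerance = 1e-12)
})

test_that("the null tail of the screen is self-consistent", {
  set.seed(10)
  on_a <- matrix(runif(120 * 26) < 0.4, 120, 26,
                 dimnames = list(sprintf("A%03d", 1:120), NULL))
  on_b <- matrix(runif(120 * 26) < 0.4, 120, 26,
                 dimnames = list(sprintf("A%03d", 1:120), NULL))
  sc <- pairwise_mi_screen(activation_matrix(on_a, "gene set", 0.25),
                           activation_matrix(on_b, "gene set", 0.25),
                           n_perm = 150, seed = 4, n_null = 60)
  thr <- 0.15
  obs_tail <- mean(sc$table$mi_bits >= thr)
  nh <- sc$null_histogram
  tail_bins <- nh$breaks[-length(nh$breaks)] >= thr
  null_tail <- sum(nh$null_mean[tail_bins]) / nrow(sc$table)
  mc_err <- 3 * (sd(sc$table$mi_bits >= thr) / sqrt(nrow(sc$table)) +
                 sqrt(sum(nh$null_sd[tail_bins]^2)) / nrow(sc$table) /
                 sqrt(nh$n_null))
  expect_lt(abs(obs_tail - null_tail), mc_err + 0.02)
})

test_that("unmapped identifiers are reported by name", {
  on <- matrix(TRUE, 2, 4, dimnames = list(c("a", "b"), NULL))
  a <- activation_matrix(on, "gene set", 0.25)
  bad <- ortholog_map(data.frame(id_a = c("a", "zz"), id_b = c("a", "b")))
  expect_error(pairwise_mi_screen(a, a, bad, n_perm = 100), "zz")
})

test_that("many-to-many ortholog pairs are kept with their multiplicity", {
  set.seed(6)
  on <- matrix(runif(3 * 10) < 0.5, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  act <- activation_matrix(on, "gene set", 0.25)
  map <- ortholog_map(data.frame(id_a = c("a", "a", "b", "c", "a"),
                                 id_b = c("a", "b", "a", "c", "b")))
  sc <- pairwise_mi_screen(act, act, map, n_perm = 100, seed = 1, n_null = 5)
  expect_equal(nrow(sc$table), 5L)         # duplicate a->b retained
  dup <- sc$table[sc$table$id_a == "a" & sc$table$id_b == "b", ]
  expect_equal(nrow(dup), 2L)
  expect_equal(dup$mi_bits[1], dup$mi_bits[2])
})
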