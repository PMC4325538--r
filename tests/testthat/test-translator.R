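test_that("PCA captures rank-1 structure and reconstructs exactly", {
  u <- rnorm(30); v <- rnorm(10)
  m <- outer(u, v)
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10))
  pca <- fit_pca(m, 1)
  expect_gt(pca$component_variances[1] / sum(pca$component_variances), 0.999)

  set.seed(1)
  m2 <- matrix(rnorm(15 * 6), 15, 6,
               dimnames = list(sprintf("g%02d", 1:15), sprintf("s%d", 1:6)))
  pca2 <- fit_pca(m2, 5)
  recon <- pca2$scores %*% t(pca2$loadings)
  centered <- sweep(t(m2), 2L, pca2$center)
  expect_equal(recon, centered, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(crossprod(pca2$loadings), diag(5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diff(pca2$component_variances) <= 1e-12))
  expect_error(fit_pca(m2, 6), "rank")
})

test_that("posteriors match the brute-force pooled-diagonal Gaussian oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n_tr <- 8; n_comp <- 3; n_sets <- 6
    nes <- matrix(rnorm(40 * (n_tr + 4)), 40,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("s%02d", 1:(n_tr + 4))))
    pca <- fit_pca(nes, n_comp)
    train <- sprintf("s%02d", 1:n_tr)
    test <- sprintf("s%02d", (n_tr + 1):(n_tr + 4))
    lab <- matrix(runif(n_sets * n_tr) < 0.5, n_sets, n_tr,
                  dimnames = list(sprintf("GS%d", 1:n_sets), train))
    lab[1, ] <- c(rep(TRUE, 4), rep(FALSE, 4))  # ensure a two-class set
    labels <- activation_matrix(lab, "gene set", 0.25)
    clf <- train_genesets_classifier(pca, train, labels, n_comp)
    p <- predict(clf, pca, test)
    z_tr <- pca$scores[train, 1:n_comp]
    z_te <- pca$scores[test, 1:n_comp]
    for (g in seq_len(n_sets)) {
      y <- lab[g, ]
      expected <- if (all(y) || !any(y)) rep(mean(y), 4)
                  else posterior_oracle(z_tr, y, z_te)
      expect_equal(unname(p[g, ]), unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("single-class gene sets degenerate to their empirical prior", {
  set.seed(2)
  nes <- matrix(rnorm(20 * 8), 20, dimnames = list(NULL, sprintf("s%d", 1:8)))
  pca <- fit_pca(nes, 2)
  lab <- rbind(alloff = rep(FALSE, 6), allon = rep(TRUE, 6),
               mixed = rep(c(TRUE, FALSE), 3))
  colnames(lab) <- sprintf("s%d", 1:6)
  labels <- activation_matrix(lab, "gene set", 0.25)
  clf <- train_genesets_classifier(pca, colnames(lab), labels, 2)
  expect_identical(clf$degenerate, c(alloff = TRUE, allon = TRUE, mixed = FALSE))
  p <- predict(clf, pca, sprintf("s%d", 7:8))
  expect_true(all(p["alloff", ] == 0))
  expect_true(all(p["allon", ] == 1))
})

test_that("symmetric equal clouds put the boundary at the bisector", {
  # two clouds symmetric about 0 along PC1, equal sizes: posterior is 0.5 at
  # the midpoint and favors each class on its own side
  nes <- t(cbind(c(-3, -2.5, -2, 2, 2.5, 3), c(0.5, -0.5, 0.1, 0.1, -0.5, 0.5)))
  rownames(nes) <- c("gA", "gB")
  colnames(nes) <- sprintf("s%d", 1:6)
  pca <- fit_pca(nes, 1)
  on_side <- pca$scores[, 1] > 0
  lab <- matrix(on_side, 1, 6, dimnames = list("GS1", colnames(nes)))
  labels <- activation_matrix(lab, "gene set", 0.25)
  clf <- train_genesets_classifier(pca, colnames(nes), labels, 1)
  sc_mid <- (clf$means_on[1, 1] + clf$means_off[1, 1]) / 2
  pca_q <- pca
  pca_q$scores <- rbind(pca$scores, mid = sc_mid, onside = sc_mid + 2,
                        offside = sc_mid - 2)
  p <- predict(clf, pca_q, c("mid", "onside", "offside"))
  expect_equal(p[1, "mid"], 0.5, tolerance = 1e-9)
  expect_gt(p[1, "onside"], 0.9)
  expect_lt(p[1, "offside"], 0.1)
})

test_that("LOO ensemble respects the probability contract and orderings", {
  tr <- generate_translation_dataset(synth_translation_config(
    n_genesets = 40, seed = 19))
  labels <- binarize_genesets(tr$human_a)
  pca <- fit_pca(tr$rat_nes, 8)
  pred <- predict_loo_ensemble(pca, labels, tr$train_stimuli, tr$test_stimuli, 8)
  expect_true(all(pred$p_on >= 0 & pred$p_on <= 1))
  expect_identical(dim(pred$p_on), c(40L, 26L))

  # row/column order invariance
  perm_sets <- sample(rownames(tr$rat_nes$nes))
  nes_p <- tr$rat_nes$nes[perm_sets, ]
  labels_p <- activation_matrix(labels$on[perm_sets, ], "gene set", 0.25)
  pred_p <- predict_loo_ensemble(fit_pca(nes_p, 8), labels_p,
                                 tr$train_stimuli, rev(tr$test_stimuli), 8)
  expect_equal(pred_p$p_on[rownames(pred$p_on), colnames(pred$p_on)],
               pred$p_on, tolerance = 1e-9)
})

test_that("adversarial inputs keep posteriors inside [0, 1]", {
  set.seed(14)
  nes <- matrix(rep(rnorm(8), each = 12), 12, byrow = FALSE)
  nes <- rbind(nes, nes[1, ], nes[1, ])            # collinear gene sets
  nes[, 5] <- nes[, 4]                             # duplicated stimulus
  nes <- nes + rnorm(length(nes), sd = 1e-4)       # near-degenerate, full rank
  dimnames(nes) <- list(sprintf("g%02d", 1:14), sprintf("s%d", 1:8))
  pca <- fit_pca(nes, 2)
  lab <- matrix(rep(c(TRUE, FALSE), 7), 14, 5,
                dimnames = list(rownames(nes), sprintf("s%d", 1:5)))
  labels <- activation_matrix(lab, "gene set", 0.25)
  pred <- suppressWarnings(
    predict_loo_ensemble(pca, labels, sprintf("s%d", 1:5),
                         sprintf("s%d", 6:8), 2))
  expect_true(all(is.finite(pred$p_on)))
  expect_true(all(pred$p_on >= 0 & pred$p_on <= 1))
})

test_that("the transductive PCA fit is load-bearing", {
  tr <- generate_translation_dataset(synth_translation_config(
    n_genesets = 50, seed = 28))
  labels <- binarize_genesets(tr$human_a)
  pca_all <- fit_pca(tr$rat_nes, 6)
  pred_all <- predict_loo_ensemble(pca_all, labels, tr$train_stimuli,
                                   tr$test_stimuli, 6)
  # train-only fit, test stimuli projected afterwards
  pca_tr <- fit_pca(tr$rat_nes$nes[, tr$train_stimuli], 6)
  sc <- sweep(t(tr$rat_nes$nes), 2L, pca_tr$center) %*% pca_tr$loadings
  pca_tr$scores <- sc
  pred_tr <- predict_loo_ensemble(pca_tr, labels, tr$train_stimuli,
                                  tr$test_stimuli, 6)
  expect_gt(max(abs(pred_all$p_on - pred_tr$p_on)), 1e-6)
})

test_that("full-covariance option runs and stays probabilistic", {
  tr <- generate_translation_dataset(synth_translation_config(
    n_genesets = 20, seed = 33))
  labels <- binarize_genesets(tr$human_a)
  pca <- fit_pca(tr$rat_nes, 4)
  pred <- predict_loo_ensemble(pca, labels, tr$train_stimuli,
                               tr$test_stimuli, 4, covariance = "full")
  expect_true(all(pred$p_on >= 0 & pred$p_on <= 1))
})

test_that("rank-1 noiseless selection saturates at N = 1", {
  tr <- generate_translation_dataset(synth_translation_config(
    n_genesets = 40, latent_rank = 1, nes_noise_sd = 1e-4,
    human_label_noise = 0, frac_anticorrelated = 0, seed = 3))
  labels <- binarize_genesets(tr$human_a)
  # components beyond the latent rank have ~zero variance: flooring warns
  sel <- suppressWarnings(
    select_n_components(tr$rat_nes, labels, tr$train_stimuli, 1:4))
  expect_gt(sel$table$auroc[1], 0.95)
  expect_lt(max(sel$table$auroc) - sel$table$auroc[1], 0.02)
  # argmax guarantees best N is at least as good as N = 1
  expect_gte(sel$table$auroc[sel$table$n == sel$best_n], sel$table$auroc[1])
  expect_error(select_n_components(tr$rat_nes, labels, tr$train_stimuli, 1:30),
               "n_train")
})

test_that("flip-noise 0.5 reduces the ensemble to chance", {
  aucs <- vapply(1:4, function(s) {
    tr <- generate_translation_dataset(synth_translation_config(
      n_genesets = 80, human_label_noise = 0.49, seed = 600 + s))
    labels <- binarize_genesets(tr$human_a)
    pca <- fit_pca(tr$rat_nes, 8)
    pred <- predict_loo_ensemble(pca, labels, tr$train_stimuli, tr$test_stimuli, 8)
    auroc_score(as.vector(pred$p_on), as.vector(tr$human_b_gold$on))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})
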