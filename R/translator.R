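#' Principal component analysis of a gene-set score matrix
#'
#' Stimuli are treated as samples and gene sets as variables: each gene set
#' is mean-centered over all stimuli (no variance scaling — NES values are
#' already normalized) and the leading components of variation across
#' stimuli are extracted.  The pipeline fits this on the *combined*
#' train-plus-test stimulus matrix (transductive by design), so test stimuli
#' shape the coordinate system even though their labels are never seen.
#'
#' @param scores a [geneset_scores] object or a gene set x stimulus matrix.
#' @param n_components number of leading components to keep.
#'
#' @return An object of class `pca_model` with `loadings` (gene set x
#'   component, orthonormal columns), `scores` (stimulus x component),
#'   `component_variances` (all, non-increasing), `center` (per-gene-set
#'   means) and `n_components_kept`.
#' @export
fit_pca <- function(scores, n_components) {
  nes <- if (inherits(scores, "geneset_scores")) scores$nes else as.matrix(scores)
  x <- t(nes)                                  # stimuli x gene sets
  if (nrow(x) < 2L) stop("need at least two stimuli")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  rank <- sum(sv$d > max(sv$d) * max(dim(xc)) * .Machine$double.eps)
  if (n_components > rank)
    stop(sprintf("n_components (%d) exceeds the matrix rank (%d)",
                 n_components, rank))
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  sc <- xc %*% loadings
  rownames(loadings) <- rownames(nes)
  rownames(sc) <- colnames(nes)
  colnames(loadings) <- colnames(sc) <- sprintf("PC%d", keep)
  structure(list(loadings = loadings, scores = sc,
                 component_variances = sv$d^2 / (nrow(x) - 1L),
                 center = ctr, n_components_kept = as.integer(n_components),
                 rank = rank),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  v <- x$component_variances
  cat(sprintf("<pca_model> %d components kept of rank %d; leading variance share %.1f%%\n",
              x$n_components_kept, x$rank, 100 * v[1L] / sum(v)))
  invisible(x)
}

#' Train per-gene-set pooled-diagonal Gaussian classifiers
#'
#' For every gene set, the training stimuli (points in the space of the `N`
#' leading principal-component scores) are split by the gene set's human
#' on/off label and a two-class Gaussian model is fitted: per-class means, a
#' pooled per-dimension variance with off-diagonal covariances set to zero
#' (a naive Bayes classifier), and empirical class priors.  The `"full"`
#' covariance option pools the full covariance matrix instead (linear
#' discriminant analysis); it is provided for comparison and is not the
#' default.
#'
#' Gene sets whose training labels are single-class are flagged degenerate;
#' their posterior is the empirical prior (0 or 1).  Pooled variances of
#' exactly zero in a dimension are floored at `1e-8` times the gene set's
#' mean pooled variance, with a warning.
#'
#' @param pca a [pca_model][fit_pca] whose scores cover the training stimuli.
#' @param train_stimulus_ids character vector of training stimulus ids.
#' @param human_labels an [activation_matrix] whose columns cover the
#'   training stimuli.
#' @param n_components number N of leading components to use (defaults to
#'   all kept components).
#' @param covariance `"diagonal"` (default) or `"full"`.
#'
#' @return An object of class `geneset_classifier`.
#' @export
train_genesets_classifier <- function(pca, train_stimulus_ids, human_labels,
                                      n_components = pca$n_components_kept,
                                      covariance = c("diagonal", "full")) {
  stopifnot(inherits(pca, "pca_model"), inherits(human_labels, "activation_matrix"))
  covariance <- match.arg(covariance)
  if (n_components > pca$n_components_kept)
    stop("n_components exceeds the components kept in the PCA model")
  missing_stim <- setdiff(train_stimulus_ids, rownames(pca$scores))
  if (length(missing_stim))
    stop("training stimuli absent from PCA scores: ",
         paste(missing_stim, collapse = ", "))
  if (!all(train_stimulus_ids %in% colnames(human_labels$on)))
    stop("labels do not cover all training stimuli")

  z <- pca$scores[train_stimulus_ids, seq_len(n_components), drop = FALSE]
  lab <- human_labels$on[, train_stimulus_ids, drop = FALSE] * 1
  n <- length(train_stimulus_ids)
  n1 <- rowSums(lab); n0 <- n - n1
  degenerate <- n1 == 0 | n0 == 0

  m1 <- (lab %*% z) / pmax(n1, 1L)
  m0 <- ((1 - lab) %*% z) / pmax(n0, 1L)
  s1 <- lab %*% z^2
  s0 <- (1 - lab) %*% z^2
  pooled <- (s1 - n1 * m1^2 + s0 - n0 * m0^2) / pmax(n - 2L, 1L)
  pooled <- pmax(pooled, 0)

  vfloor <- 1e-8 * pmax(rowMeans(pooled), .Machine$double.eps)
  zero_var <- pooled < vfloor & !degenerate
  if (any(zero_var)) {
    warning(sprintf("%d pooled variances floored", sum(zero_var)))
    pooled[zero_var] <- vfloor[row(pooled)[zero_var]]
  }
  pooled[degenerate, ] <- 1  # unused; keeps densities finite

  cov_list <- NULL
  if (covariance == "full") {
    cov_list <- lapply(seq_len(nrow(lab)), function(g) {
      if (degenerate[g]) return(diag(n_components))
      on <- lab[g, ] > 0
      d1 <- sweep(z[on, , drop = FALSE], 2L, m1[g, ])
      d0 <- sweep(z[!on, , drop = FALSE], 2L, m0[g, ])
      sig <- (crossprod(d1) + crossprod(d0)) / (n - 2L)
      sig + diag(1e-8 * mean(diag(sig)) + .Machine$double.eps, n_components)
    })
  }

  structure(list(means_on = m1, means_off = m0, pooled_var = pooled,
                 cov_list = cov_list, prior_on = n1 / n, n_on = n1,
                 n_off = n0, degenerate = degenerate,
                 n_components = as.integer(n_components),
                 covariance = covariance, set_ids = rownames(lab),
                 train_stimulus_ids = train_stimulus_ids),
            class = "geneset_classifier")
}

#' @export
print.geneset_classifier <- function(x, ...) {
  cat(sprintf("<geneset_classifier> %d gene sets, %d components, %s covariance, %d degenerate\n",
              length(x$set_ids), x$n_components, x$covariance,
              sum(x$degenerate)))
  invisible(x)
}

#' Posterior on-probabilities from a trained gene-set classifier
#'
#' @param object a [geneset_classifier][train_genesets_classifier].
#' @param pca the [pca_model][fit_pca] providing scores for the query
#'   stimuli.
#' @param stimulus_ids stimuli to predict.
#' @param ... unused.
#'
#' @return Numeric matrix of posterior on-probabilities, gene sets x query
#'   stimuli, values in \[0, 1\].
#' @export
predict.geneset_classifier <- function(object, pca, stimulus_ids, ...) {
  z <- pca$scores[stimulus_ids, seq_len(object$n_components), drop = FALSE]
  p <- if (object$covariance == "diagonal") {
    w <- 1 / object$pooled_var
    q <- w %*% t(z^2)
    l1 <- (object$means_on * w) %*% t(z)
    l0 <- (object$means_off * w) %*% t(z)
    c1 <- rowSums(object$means_on^2 * w)
    c0 <- rowSums(object$means_off^2 * w)
    log1p_ <- log(object$prior_on)
    log0p_ <- log(1 - object$prior_on)
    d1 <- -0.5 * (q - 2 * l1 + c1) + log1p_
    d0 <- -0.5 * (q - 2 * l0 + c0) + log0p_
    1 / (1 + exp(d0 - d1))
  } else {
    out <- matrix(NA_real_, length(object$set_ids), nrow(z))
    for (g in seq_along(object$set_ids)) {
      if (object$degenerate[g]) next
      sig_inv <- solve(object$cov_list[[g]])
      d1v <- sweep(z, 2L, object$means_on[g, ])
      d0v <- sweep(z, 2L, object$means_off[g, ])
      q1 <- rowSums((d1v %*% sig_inv) * d1v)
      q0 <- rowSums((d0v %*% sig_inv) * d0v)
      l1 <- -0.5 * q1 + log(object$prior_on[g])
      l0 <- -0.5 * q0 + log(1 - object$prior_on[g])
      out[g, ] <- 1 / (1 + exp(l0 - l1))
    }
    out
  }
  if (any(object$degenerate))
    p[object$degenerate, ] <- object$prior_on[object$degenerate]
  dimnames(p) <- list(object$set_ids, stimulus_ids)
  p
}

#' Leave-one-out ensemble prediction of human gene-set activation
#'
#' For every leave-one-out fold over the training stimuli, the per-gene-set
#' classifiers are retrained on the remaining stimuli and evaluated on every
#' test stimulus; the final on-probability is the arithmetic mean over
#' folds.  Folds whose training labels collapse to a single class
#' contribute their empirical prior (0 or 1).
#'
#' @param pca a transductive [pca_model][fit_pca] covering train and test
#'   stimuli.
#' @param human_labels an [activation_matrix] over the training stimuli.
#' @param train_stimulus_ids,test_stimulus_ids stimulus id vectors.
#' @param n_components number of leading components (default 8, the design
#'   optimum).
#' @param covariance `"diagonal"` (default) or `"full"`.
#'
#' @return An object of class `prediction_matrix` with `p_on` (gene set x
#'   test stimulus posteriors in \[0, 1\]) and provenance fields.
#' @export
predict_loo_ensemble <- function(pca, human_labels, train_stimulus_ids,
                                 test_stimulus_ids, n_components = 8L,
                                 covariance = c("diagonal", "full")) {
  covariance <- match.arg(covariance)
  if (length(train_stimulus_ids) < 3L)
    stop("need at least 3 training stimuli for leave-one-out folds")
  acc <- NULL
  for (i in seq_along(train_stimulus_ids)) {
    clf <- train_genesets_classifier(pca, train_stimulus_ids[-i],
                                     human_labels, n_components, covariance)
    p <- predict(clf, pca, test_stimulus_ids)
    acc <- if (is.null(acc)) p else acc + p
  }
  p_on <- acc / length(train_stimulus_ids)
  structure(list(p_on = p_on, n_components = as.integer(n_components),
                 n_folds = length(train_stimulus_ids),
                 covariance = covariance),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d gene sets x %d stimuli (N = %d, %d folds, %s covariance)\n",
              nrow(x$p_on), ncol(x$p_on), x$n_components, x$n_folds,
              x$covariance))
  invisible(x)
}

#' Select the number of principal components by internal leave-one-out
#'
#' Each training stimulus is predicted in turn from a classifier trained on
#' the remaining training stimuli (single model per fold, no inner
#' ensemble); the collected posteriors are scored against the known labels
#' with AUROC, Pearson correlation (against the binary labels and, when an
#' FDR matrix is supplied, against `1 - FDR`) and the Matthews correlation
#' coefficient.  The best N maximizes the designated metric.
#'
#' @param scores rat NES as a [geneset_scores] or matrix, covering all
#'   stimuli used for the (transductive) PCA fit.
#' @param human_labels [activation_matrix] over the training stimuli.
#' @param train_stimulus_ids stimuli with known labels.
#' @param candidate_ns candidate component counts (each < number of training
#'   stimuli).
#' @param metric metric maximized (`"auroc"` default, or
#'   `"pearson_binary"`, `"pearson_continuous"`, `"mcc"`).
#' @param gold_fdr optional [geneset_scores] carrying the training FDR
#'   matrix for the continuous Pearson metric.
#' @param covariance passed to the classifier.
#'
#' @return A list with `best_n` and `table`, a data.frame of all metrics per
#'   candidate N (NA where a metric is undefined; such N are skipped by the
#'   argmax).
#' @export
select_n_components <- function(scores, human_labels, train_stimulus_ids,
                                candidate_ns = 1:12, metric = "auroc",
                                gold_fdr = NULL,
                                covariance = c("diagonal", "full")) {
  covariance <- match.arg(covariance)
  n_train <- length(train_stimulus_ids)
  if (any(candidate_ns < 1L) || any(candidate_ns >= n_train))
    stop("candidate_ns must lie in [1, n_train - 1]")
  pca <- fit_pca(scores, max(candidate_ns))
  lab <- human_labels$on[, train_stimulus_ids, drop = FALSE]
  cont <- if (!is.null(gold_fdr))
    continuous_activation(gold_fdr)[rownames(lab), train_stimulus_ids, drop = FALSE]

  rows <- lapply(candidate_ns, function(nn) {
    p <- matrix(NA_real_, nrow(lab), n_train, dimnames = dimnames(lab))
    for (i in seq_len(n_train)) {
      clf <- train_genesets_classifier(pca, train_stimulus_ids[-i],
                                       human_labels, nn, covariance)
      p[, i] <- predict(clf, pca, train_stimulus_ids[i])[, 1L]
    }
    pv <- as.vector(p); lv <- as.vector(lab)
    data.frame(
      n = nn,
      auroc = auroc_score(pv, lv),
      pearson_binary = safe_cor(pv, lv * 1),
      pearson_continuous = if (is.null(cont)) NA_real_
                           else safe_cor(pv, as.vector(cont)),
      mcc = mcc_score(pv >= 0.5, lv))
  })
  tab <- do.call(rbind, rows)
  vals <- tab[[metric]]
  if (all(is.na(vals))) stop("designated metric undefined for every candidate N")
  list(best_n = tab$n[which.max(vals)], table = tab)
}
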