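#' Threshold-free and thresholded classification metrics
#'
#' `auroc_score` uses the midrank (Mann-Whitney) estimator, equivalent to
#' trapezoidal integration of the ROC curve with tied scores averaged.
#' `aupr_score` sweeps distinct score thresholds from high to low and
#' accumulates step-wise precision-recall area (average precision; no linear
#' PR interpolation).  `bac_score` and `mcc_score` evaluate binary decisions.
#' Metrics undefined on single-class inputs return `NA`.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (or 0/1) true labels.
#' @param calls logical predicted classes.
#' @return A single number (or `NA` when undefined).
#' @export
auroc_score <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auroc_score
#' @export
aupr_score <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels)
  if (n1 == 0L || all(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # evaluate only at the last index of each tied score block
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' @rdname auroc_score
#' @export
bac_score <- function(calls, labels) {
  ok <- !is.na(calls) & !is.na(labels)
  calls <- as.logical(calls[ok]); labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  sens <- sum(calls & labels) / n1
  spec <- sum(!calls & !labels) / n0
  (sens + spec) / 2
}

#' @rdname auroc_score
#' @export
mcc_score <- function(calls, labels) {
  ok <- !is.na(calls) & !is.na(labels)
  calls <- as.logical(calls[ok]); labels <- as.logical(labels[ok])
  tp <- sum(calls & labels); tn <- sum(!calls & !labels)
  fp <- sum(calls & !labels); fn <- sum(!calls & labels)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

safe_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Score a prediction matrix against a gold standard
#'
#' Gene-set x stimulus cells are flattened and the challenge metrics
#' computed: AUPR and AUROC by rank sweep over the posterior
#' on-probabilities, balanced accuracy and Matthews correlation at the
#' decision rule `p_on >= 0.5`, and Pearson correlations of the posterior
#' against the binary labels and (when the gold FDR matrix is available)
#' against `1 - FDR`.
#'
#' @param predictions a [prediction_matrix][predict_loo_ensemble] or a bare
#'   numeric matrix of posteriors.
#' @param gold an [activation_matrix] with the same shape.
#' @param gold_fdr optional [geneset_scores] carrying the gold FDR matrix.
#'
#' @return An object of class `evaluation_report`: `aupr`, `auroc`,
#'   `pearson_binary`, `pearson_continuous`, `bac`, `mcc`, `n_positives`,
#'   `n_negatives`.  Metrics undefined for the input (single-class gold,
#'   constant predictions) are `NA`, never 0.
#' @export
score_predictions <- function(predictions, gold, gold_fdr = NULL) {
  p <- if (inherits(predictions, "prediction_matrix")) predictions$p_on
       else as.matrix(predictions)
  stopifnot(inherits(gold, "activation_matrix"))
  if (!identical(dim(p), dim(gold$on)))
    stop("prediction and gold matrices have different shapes")
  pv <- as.vector(p); lv <- as.vector(gold$on)
  cont <- if (!is.null(gold_fdr)) as.vector(continuous_activation(gold_fdr))
  structure(list(
    aupr = aupr_score(pv, lv),
    auroc = auroc_score(pv, lv),
    pearson_binary = safe_cor(pv, lv * 1),
    pearson_continuous = if (is.null(cont)) NA_real_ else safe_cor(pv, cont),
    bac = bac_score(pv >= 0.5, lv),
    mcc = mcc_score(pv >= 0.5, lv),
    n_positives = sum(lv, na.rm = TRUE),
    n_negatives = sum(!lv, na.rm = TRUE)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> AUPR %.3f | AUROC %.3f | Pearson %.3f",
                     " (cont %.3f) | BAC %.3f | MCC %.3f  [%d+/%d-]\n"),
              x$aupr, x$auroc, x$pearson_binary, x$pearson_continuous,
              x$bac, x$mcc, x$n_positives, x$n_negatives))
  invisible(x)
}

#' Rank robustness of competing predictions under gold-standard resampling
#'
#' Emulates the challenge organizers' robustness procedure: in each
#' resample, a stratified fraction of the gold-standard cells is drawn
#' (preserving the positive/negative class proportion to within one cell),
#' every method is re-scored on those cells with AUPR, Pearson (binary) and
#' BAC, methods are ranked by their sum of ranks over the three metrics
#' (average ranks on ties, higher metric = better rank), and the per-method
#' rank distribution accumulated.
#'
#' @param prediction_sets named list of two or more prediction matrices
#'   (or [prediction_matrix][predict_loo_ensemble] objects), all the same
#'   shape as `gold`.
#' @param gold an [activation_matrix].
#' @param fraction fraction of gold cells per resample (default 0.1).
#' @param n_resamples number of resamples (default 1000).
#' @param seed integer seed.
#'
#' @return An object of class `robustness_summary` with `rank_matrix`
#'   (methods x resamples), `first_fraction` (share of resamples each method
#'   ranks first, ties split), `fraction`, `n_resamples`, `seed`.
#' @export
robustness_resample <- function(prediction_sets, gold, fraction = 0.1,
                                n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(gold, "activation_matrix"))
  if (length(prediction_sets) < 2L) stop("need at least two prediction sets")
  mats <- lapply(prediction_sets, function(p)
    as.vector(if (inherits(p, "prediction_matrix")) p$p_on else as.matrix(p)))
  lv <- as.vector(gold$on)
  ok <- !is.na(lv)
  lv <- lv[ok]; mats <- lapply(mats, `[`, ok)
  pos <- which(lv); neg <- which(!lv)
  k_pos <- round(fraction * length(pos)); k_neg <- round(fraction * length(neg))
  if (k_pos < 1L || k_neg < 1L)
    stop("resample fraction leaves a class empty")
  set.seed(seed)
  nm <- names(prediction_sets) %||% sprintf("method%d", seq_along(mats))

  rank_matrix <- matrix(NA_real_, length(mats), n_resamples,
                        dimnames = list(nm, NULL))
  first_w <- numeric(length(mats))
  for (r in seq_len(n_resamples)) {
    cells <- c(sample(pos, k_pos), sample(neg, k_neg))
    l <- lv[cells]
    met <- vapply(mats, function(m) {
      s <- m[cells]
      c(aupr_score(s, l), safe_cor(s, l * 1), bac_score(s >= 0.5, l))
    }, numeric(3L))
    # higher is better for all three; rank 1 = best after summing ranks
    ranks_per_metric <- apply(met, 1L, function(v) rank(-v, na.last = "keep"))
    sums <- rowSums(ranks_per_metric)
    rank_matrix[, r] <- rank(sums)
    best <- sums == min(sums)
    first_w[best] <- first_w[best] + 1 / sum(best)
  }
  structure(list(rank_matrix = rank_matrix,
                 first_fraction = stats::setNames(first_w / n_resamples, nm),
                 fraction = fraction, n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("<robustness_summary> %d resamples at fraction %g\n",
              x$n_resamples, x$fraction))
  for (nm in rownames(x$rank_matrix))
    cat(sprintf("  %s: mean rank %.2f, first in %.1f%% of resamples\n", nm,
                mean(x$rank_matrix[nm, ]), 100 * x$first_fraction[nm]))
  invisible(x)
}
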