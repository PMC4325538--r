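#' Call differentially expressed genes with curve-derived SDs
#'
#' For every (gene, stimulus) pair the mean of the surviving treated
#' replicates is compared with the mean of the gene's control replicates by a
#' two-sample test in which both group standard deviations are replaced by
#' the universal-curve SD interpolated at each group's mean (the curve must
#' be estimated in the same — typically linearized — space as `cleaned`).
#' The statistic is
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with `s1`, `s2` taken from the
#' curve.
#'
#' Because the curve SD pools thousands of replicate groups it is essentially
#' the known noise SD, so under Gaussian noise the statistic is a standard
#' normal and the default reference distribution is `"normal"`; this keeps
#' the test calibrated at its nominal level.  `df_method = "pooled"` instead
#' uses a t reference with `n1 + n2 - 2` degrees of freedom, the conventional
#' two-sample choice, which is conservative when the SD is effectively known.
#'
#' @param cleaned an outlier-cleaned (and linearized) [replicate_set].
#' @param curve the [noise_curve][build_noise_curve] estimated on the same
#'   (linearized) data.
#' @param alpha significance threshold on the two-sided p-value
#'   (default 0.01; strictly-less comparison, so ties stay uncalled).
#' @param df_method `"normal"` (default) or `"pooled"` (t with n1+n2-2 df).
#'
#' @return An object of class `differential_calls` with matrices `p_values`,
#'   `calls` (logical; `NA` for discarded pairs), `effect` (treated minus
#'   control mean), `t_stat`, and the threshold used.
#' @export
call_differential_genes <- function(cleaned, curve, alpha = 0.01,
                                    df_method = c("normal", "pooled")) {
  stopifnot(inherits(cleaned, "replicate_set"), inherits(curve, "noise_curve"))
  df_method <- match.arg(df_method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")

  tm <- pair_moments(cleaned$values)
  d <- dim(cleaned$values)
  m1 <- matrix(tm$mean, d[1L], d[2L])
  n1 <- matrix(tm$n, d[1L], d[2L])
  cm <- group_moments(cleaned$control_values)
  m2 <- cm$mean; n2 <- cm$n

  ok <- n1 >= 2L & matrix(n2 >= 2L, d[1L], d[2L])
  s1 <- matrix(NA_real_, d[1L], d[2L])
  s1[ok] <- interpolate_sd(curve, m1[ok])
  s2 <- rep(NA_real_, d[1L])
  s2[n2 >= 2L] <- interpolate_sd(curve, m2[n2 >= 2L])
  if (any(s1[ok] <= 0, na.rm = TRUE) || any(s2 <= 0, na.rm = TRUE))
    stop("universal curve returned a zero SD")

  se <- sqrt(s1^2 / n1 + matrix(s2^2 / n2, d[1L], d[2L]))
  tstat <- (m1 - m2) / se
  tstat[!ok] <- NA_real_
  p <- if (df_method == "normal") {
    2 * pnorm(-abs(tstat))
  } else {
    df <- n1 + matrix(n2, d[1L], d[2L]) - 2L
    2 * pt(-abs(tstat), df = df)
  }
  calls <- p < alpha
  eff <- m1 - m2
  eff[!ok] <- NA_real_
  dn <- list(cleaned$gene_ids, cleaned$stimulus_ids)
  dimnames(p) <- dimnames(calls) <- dimnames(eff) <- dimnames(tstat) <- dn
  structure(list(p_values = p, calls = calls, effect = eff, t_stat = tstat,
                 threshold = alpha, df_method = df_method),
            class = "differential_calls")
}

#' @export
print.differential_calls <- function(x, ...) {
  cat(sprintf("<differential_calls> %d x %d, %d called at p < %g (%s reference), %d missing\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls, na.rm = TRUE),
              x$threshold, x$df_method, sum(is.na(x$calls))))
  invisible(x)
}

#' Convert differential calls to a binary activation matrix
#'
#' @param calls a [differential_calls][call_differential_genes] object.
#' @return An [activation_matrix] with source `"gene"`.
#' @export
calls_to_activation <- function(calls) {
  stopifnot(inherits(calls, "differential_calls"))
  activation_matrix(calls$calls, source = "gene", threshold = calls$threshold)
}

#' Binarize a gene-set score matrix at an FDR threshold
#'
#' A gene set is ON for a stimulus when its FDR is strictly below `fdr_cut`
#' (ties at the threshold stay OFF).
#'
#' @param scores a [geneset_scores] object with an FDR matrix.
#' @param fdr_cut FDR threshold (default 0.25).
#'
#' @return An [activation_matrix] with the same labels as the input.
#' @export
binarize_genesets <- function(scores, fdr_cut = 0.25) {
  stopifnot(inherits(scores, "geneset_scores"))
  if (is.null(scores$fdr)) stop("score matrix carries no FDR values")
  if (any(scores$fdr < 0 | scores$fdr > 1, na.rm = TRUE))
    stop("FDR values outside [0, 1]")
  activation_matrix(scores$fdr < fdr_cut, source = "gene set",
                    threshold = fdr_cut)
}

#' Continuous activation scale from FDR values
#'
#' Returns `1 - FDR` elementwise: a continuous confidence-of-activation
#' scale used when correlating predictions against a non-binarized gold
#' standard.
#'
#' @param scores a [geneset_scores] object with an FDR matrix.
#' @return Numeric matrix, same shape and labels as the FDR matrix.
#' @export
continuous_activation <- function(scores) {
  stopifnot(inherits(scores, "geneset_scores"))
  if (is.null(scores$fdr)) stop("score matrix carries no FDR values")
  1 - scores$fdr
}
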