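# Independent brute-force oracles and tiny fixtures used across the suite.
# Oracles deliberately take different computational routes than the package
# implementation they check.

# hand-built noise curve with given node points
make_curve <- function(means, sds, counts = rep(10L, length(means))) {
  structure(list(bin_edges = c(means[1L] - 1, means + 1),
                 bin_mean_expression = means, bin_sd = sds,
                 n_pairs_per_bin = as.integer(counts),
                 n_bins = length(means), unbiased = FALSE, log_scale = FALSE),
            class = "noise_curve")
}

flat_curve <- function(sd = 1) make_curve(c(0, 1000), c(sd, sd))

# replicate_set from a list of per-(gene,stimulus) replicate vectors
# (list indexed [[gene]][[stimulus]]) and a control matrix
make_repset <- function(treated, control) {
  ng <- length(treated); ns <- length(treated[[1L]])
  nr <- max(unlist(lapply(treated, lengths)))
  v <- array(NA_real_, c(ng, ns, nr))
  for (g in seq_len(ng)) for (s in seq_len(ns)) {
    x <- treated[[g]][[s]]
    v[g, s, seq_along(x)] <- x
  }
  replicate_set(v, as.matrix(control))
}

# binary vectors realizing a 2x2 contingency table (n11, n10, n01, n00)
vectors_from_table <- function(n11, n10, n01, n00) {
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(n11, n10, n01, n00))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n10, n01, n00))
  list(x = x, y = y)
}

# MI oracle: direct sum of p * log2(p / (p_row p_col)) over the four cells
mi_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p <- c(n11, n10, n01, n00) / n
  pr <- c(n11 + n10, n11 + n10, n01 + n00, n01 + n00) / n
  pc <- c(n11 + n01, n10 + n00, n11 + n01, n10 + n00) / n
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / (pr[pos] * pc[pos])))
}

# entropy oracle: literal evaluation of -sum p log2 p over the cell counts
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# pooled-diagonal Gaussian posterior oracle: literal density evaluation
posterior_oracle <- function(z_train, y, z_test, var_floor = TRUE) {
  n <- nrow(z_train)
  m1 <- colMeans(z_train[y, , drop = FALSE])
  m0 <- colMeans(z_train[!y, , drop = FALSE])
  ss <- colSums(sweep(z_train[y, , drop = FALSE], 2L, m1)^2) +
        colSums(sweep(z_train[!y, , drop = FALSE], 2L, m0)^2)
  v <- ss / (n - 2)
  p1 <- mean(y)
  apply(z_test, 1L, function(z) {
    d1 <- prod(dnorm(z, m1, sqrt(v))) * p1
    d0 <- prod(dnorm(z, m0, sqrt(v))) * (1 - p1)
    d1 / (d1 + d0)
  })
}

# AUROC oracle: all pairwise positive/negative comparisons, ties count half
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# AUPR oracle: precision/recall at every distinct threshold, step area
aupr_oracle <- function(scores, labels) {
  if (!any(labels) || all(labels)) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    prec[i] <- sum(called & labels) / sum(called)
    rec[i] <- sum(called & labels) / sum(labels)
  }
  sum(diff(c(0, rec)) * prec)
}

# standard pooled-variance two-sample t-test p-values, vectorized; the
# independent check for generator calibration (uses sample SDs, unlike the
# pipeline's curve-SD test)
pooled_t_pvals <- function(data) {
  v <- data$values
  d <- dim(v)
  n1 <- rowSums(!is.na(v), dims = 2L)
  m1 <- rowMeans(v, dims = 2L, na.rm = TRUE)
  ss1 <- rowSums(sweep(v, c(1, 2), m1)^2, dims = 2L, na.rm = TRUE)
  cv <- data$control_values
  n2 <- rowSums(!is.na(cv)); m2 <- rowMeans(cv, na.rm = TRUE)
  ss2 <- rowSums((cv - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + matrix(ss2, d[1L], d[2L])) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + matrix(1 / n2, d[1L], d[2L])))
  2 * pt(-abs(t), df)
}
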