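#' Estimate the universal noise curve from replicate data
#'
#' For every (gene, stimulus) pair with at least two non-missing replicates
#' (and, by default, every gene's control replicates) the replicate mean and
#' standard deviation are computed.  Pair means are binned into `n_bins`
#' equal-count bins; within each bin the SDs are averaged and the mean of the
#' member means recorded.  The result — replicate SD as a function of mean
#' expression — is the universal noise curve: under the assumption that
#' measurement noise depends only on the mean level, it characterizes the
#' noise of the whole array.
#'
#' Per-pair sample SDs from 2--6 replicates are biased low (by the Gaussian
#' factor c4(n), 0.886 at n = 3).  By default each pair's SD is divided by
#' c4(n) before averaging so the curve estimates the true SD rather than
#' about 89% of it; set `unbiased = FALSE` for raw sample-SD averaging.
#'
#' @param data a [replicate_set].
#' @param n_bins number of bins over the mean-expression range (default 14).
#' @param unbiased divide per-pair SDs by c4(n) to unbias them (default TRUE).
#' @param include_control include control replicate groups as extra pairs
#'   (default TRUE; same noise assumption, more pairs).
#' @param log_scale bin on log-means rather than raw means (default FALSE).
#'
#' @return An object of class `noise_curve` with fields `bin_edges`
#'   (n_bins + 1 edges), `bin_mean_expression`, `bin_sd`, `n_pairs_per_bin`,
#'   and the binning options used.  Empty bins are kept with `NA` summaries
#'   and a zero count.
#' @export
build_noise_curve <- function(data, n_bins = 14L, unbiased = TRUE,
                              include_control = TRUE, log_scale = FALSE) {
  stopifnot(inherits(data, "replicate_set"))
  ms <- pair_moments(data$values)
  if (include_control) {
    cm <- group_moments(data$control_values)
    ms <- list(mean = c(ms$mean, cm$mean), sd = c(ms$sd, cm$sd),
               n = c(ms$n, cm$n))
  }
  keep <- ms$n >= 2L & !is.na(ms$sd)
  if (!any(keep))
    stop("no (gene, stimulus) pair has >= 2 replicates; cannot estimate noise")
  m <- ms$mean[keep]; s <- ms$sd[keep]; n <- ms$n[keep]
  if (unbiased) s <- s / c4(n)

  bm <- if (log_scale) log(m) else m
  edges <- quantile(bm, probs = seq(0, 1, length.out = n_bins + 1L),
                    names = FALSE, type = 7)
  if (anyDuplicated(edges))
    edges <- edges + seq(0, diff(range(bm)) * 1e-9, length.out = n_bins + 1L)
  bin <- findInterval(bm, edges, rightmost.closed = TRUE, all.inside = TRUE)

  bin_mean <- bin_sd <- rep(NA_real_, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (all(counts == 0L)) stop("all noise-curve bins are empty; range misconfigured")
  pop <- which(counts > 0L)
  bin_mean[pop] <- vapply(pop, function(b) mean(m[bin == b]), 0)
  bin_sd[pop] <- vapply(pop, function(b) mean(s[bin == b]), 0)
  if (any(bin_sd[pop] <= 0)) stop("non-positive bin SD; degenerate replicates")

  if (log_scale) edges <- exp(edges)
  structure(list(bin_edges = edges, bin_mean_expression = bin_mean,
                 bin_sd = bin_sd, n_pairs_per_bin = counts,
                 n_bins = as.integer(n_bins), unbiased = unbiased,
                 log_scale = log_scale),
            class = "noise_curve")
}

#' @export
print.noise_curve <- function(x, ...) {
  pop <- sum(x$n_pairs_per_bin > 0L)
  cat(sprintf("<noise_curve> %d bins (%d populated), %d pairs, sd range [%.4g, %.4g]\n",
              x$n_bins, pop, sum(x$n_pairs_per_bin),
              min(x$bin_sd, na.rm = TRUE), max(x$bin_sd, na.rm = TRUE)))
  invisible(x)
}

# replicate mean/sd/count per (gene, stimulus) pair of a 3-d tensor
pair_moments <- function(v) {
  d <- dim(v)
  n <- rowSums(!is.na(v), dims = 2L)
  sum1 <- rowSums(v, dims = 2L, na.rm = TRUE)
  sum2 <- rowSums(v * v, dims = 2L, na.rm = TRUE)
  mean <- ifelse(n > 0L, sum1 / n, NA_real_)
  ss <- pmax(sum2 - n * mean^2, 0)
  sd <- ifelse(n >= 2L, sqrt(ss / pmax(n - 1L, 1L)), NA_real_)
  list(mean = as.vector(mean), sd = as.vector(sd), n = as.vector(n))
}

group_moments <- function(m) {
  n <- rowSums(!is.na(m))
  mean <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mean)^2, na.rm = TRUE)
  sd <- ifelse(n >= 2L, sqrt(ss / pmax(n - 1L, 1L)), NA_real_)
  list(mean = mean, sd = sd, n = n)
}

# E[sample SD] = c4(n) * sigma for Gaussian data
c4 <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

#' Interpolate the noise curve at a mean expression level
#'
#' Piecewise-linear interpolation between the populated bin representative
#' points, with constant extrapolation beyond the first and last populated
#' bins.
#'
#' @param curve a [noise_curve][build_noise_curve] object.
#' @param mean_expression numeric vector of query mean levels.
#'
#' @return Numeric vector of interpolated SDs.
#' @export
interpolate_sd <- function(curve, mean_expression) {
  stopifnot(inherits(curve, "noise_curve"))
  if (any(!is.finite(mean_expression)))
    stop("non-finite mean expression query")
  pop <- !is.na(curve$bin_sd)
  if (sum(pop) < 2L) stop("need >= 2 populated bins to interpolate")
  approx(curve$bin_mean_expression[pop], curve$bin_sd[pop],
         xout = mean_expression, rule = 2)$y
}

#' Iteratively remove outlier replicates using curve-derived SDs
#'
#' For each (gene, stimulus) pair: compute the mean of the surviving
#' replicates, look up the expected SD at that mean on the universal noise
#' curve, flag replicates deviating by more than `k_sd` SDs, and repeat until
#' no new flags appear or fewer than two replicates survive.  Pairs with at
#' most one survivor are discarded (recorded, and set entirely missing so
#' they carry no downstream calls).
#'
#' @param data a [replicate_set].
#' @param curve the [noise_curve][build_noise_curve] to interpolate SDs from.
#' @param k_sd flagging threshold in SD multiples (default 3).
#'
#' @return A list with `data` (the cleaned [replicate_set]) and `report`, an
#'   `outlier_report` with per-value flags for the treated tensor and control
#'   matrix, the discarded (gene, stimulus) pairs, and iteration counts.
#' @export
remove_outliers <- function(data, curve, k_sd = 3) {
  stopifnot(inherits(data, "replicate_set"), inherits(curve, "noise_curve"))
  v <- data$values
  d <- dim(v)
  flags <- array(FALSE, dim = d)
  iters <- matrix(0L, d[1L], d[2L])

  vm <- matrix(aperm(v, c(3L, 1L, 2L)), nrow = d[3L])  # replicates x pairs
  res <- clean_columns(vm, curve, k_sd)
  flags <- aperm(array(res$flag, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  iters <- matrix(res$iters, d[1L], d[2L])
  cleaned <- v
  cleaned[flags] <- NA_real_

  surv <- rowSums(!is.na(cleaned), dims = 2L)
  discard <- surv < 2L & matrix(colSums(!is.na(vm)) >= 1L, d[1L], d[2L])
  disc_idx <- which(discard, arr.ind = TRUE)
  discarded_pairs <- data.frame(
    gene = data$gene_ids[disc_idx[, 1L]],
    stimulus = data$stimulus_ids[disc_idx[, 2L]],
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(disc_idx)))
    cleaned[disc_idx[i, 1L], disc_idx[i, 2L], ] <- NA_real_

  cv <- data$control_values
  cres <- clean_columns(t(cv), curve, k_sd)
  cflags <- matrix(t(cres$flag), nrow(cv), ncol(cv))
  ccleaned <- cv
  ccleaned[cflags] <- NA_real_
  # a gene whose control drops below 2 survivors loses all its calls
  csurv <- rowSums(!is.na(ccleaned))
  ccleaned[csurv < 2L, ] <- NA_real_

  out <- replicate_set(cleaned, ccleaned, gene_ids = data$gene_ids,
                       stimulus_ids = data$stimulus_ids)
  report <- structure(list(flags = flags, control_flags = cflags,
                           discarded_pairs = discarded_pairs,
                           iterations_used = iters, k_sd = k_sd),
                      class = "outlier_report")
  list(data = out, report = report)
}

# Iterative flagging, vectorized over columns (one column = one replicate
# group).  Each round removes at most one replicate per group — the most
# deviant one beyond k_sd — then recomputes the mean of the survivors, so a
# single gross outlier cannot drag the whole group past the threshold.
clean_columns <- function(m, curve, k_sd) {
  flag <- is.na(m)                       # missing never counts as survivor
  injected <- is.na(m)
  iters <- integer(ncol(m))
  active <- rep(TRUE, ncol(m))
  m0 <- m
  m0[is.na(m0)] <- 0
  repeat {
    n <- colSums(!flag)
    active <- active & n >= 2L
    act <- which(active)
    if (length(act) == 0L) break
    mu <- colSums(m0[, act, drop = FALSE] * !flag[, act, drop = FALSE]) / n[act]
    sd_hat <- interpolate_sd(curve, mu)
    dev <- abs(sweep(m[, act, drop = FALSE], 2L, mu, `-`))
    dev[flag[, act, drop = FALSE]] <- -Inf
    dev[is.na(dev)] <- -Inf
    worst <- max.col(t(dev), ties.method = "first")
    worst_dev <- dev[cbind(worst, seq_along(act))]
    to_flag <- worst_dev > k_sd * sd_hat
    iters[act] <- iters[act] + 1L
    if (!any(to_flag)) break
    flag[cbind(worst[to_flag], act[to_flag])] <- TRUE
    active[act[!to_flag]] <- FALSE       # converged groups stay untouched
  }
  flag[injected] <- FALSE
  list(flag = flag, iters = iters)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d treated + %d control values flagged (> %g SD); %d pairs discarded\n",
              sum(x$flags), sum(x$control_flags), x$k_sd,
              nrow(x$discarded_pairs)))
  invisible(x)
}

#' Reconstruct the saturation curve by integrating the noise curve
#'
#' If the observed signal is `F(g)` for true signal `g`, and the true noise
#' `dg` has a constant SD, then the universal noise curve measured in
#' observed space is proportional to `dF/dg` evaluated along the curve.  The
#' true signal is therefore recovered, up to an affine transform, by
#' cumulative quadrature of `dg = dF / sd_obs(F)` on a dense grid of observed
#' values.  The affine freedom is fixed by (i) scaling so the true-space
#' noise SD equals `assumed_true_sd` and (ii) anchoring `F(g_min)` at the
#' lower end of the observed range.
#'
#' @param curve a [noise_curve][build_noise_curve].
#' @param assumed_true_sd the constant true-space noise SD used to fix the
#'   scale; either a positive number or `"first-bin"` (the SD of the first
#'   populated bin, so the low end of the range is left untouched).
#' @param n_grid number of grid points for the trapezoidal quadrature.
#' @param extend_sd how far beyond the binned mean range to tabulate, in
#'   multiples of the edge SDs (replicate values spread beyond pair means).
#'
#' @return An object of class `saturation_curve` with fields `g_grid`,
#'   `F_values` (both strictly increasing) and the interpolation rule.
#' @export
build_saturation_curve <- function(curve, assumed_true_sd = "first-bin",
                                   n_grid = 2048L, extend_sd = 6) {
  stopifnot(inherits(curve, "noise_curve"))
  pop <- !is.na(curve$bin_sd)
  if (identical(assumed_true_sd, "first-bin")) {
    s <- curve$bin_sd[which(pop)[1L]]
  } else {
    s <- as.numeric(assumed_true_sd)
  }
  if (!is.finite(s) || s <= 0) stop("assumed_true_sd must be positive")

  lo <- min(curve$bin_edges) - extend_sd * curve$bin_sd[which(pop)[1L]]
  hi <- max(curve$bin_edges) + extend_sd * curve$bin_sd[rev(which(pop))[1L]]
  f_grid <- seq(lo, hi, length.out = n_grid)
  sd_obs <- interpolate_sd(curve, f_grid)
  if (any(sd_obs <= 0)) stop("interpolated SD non-positive; cannot integrate")

  integrand <- 1 / sd_obs
  dg <- c(0, cumsum((integrand[-1L] + integrand[-n_grid]) / 2 * diff(f_grid)))
  g <- s * dg
  g <- g - g[1L] + f_grid[1L]            # anchor the low end of the range
  if (any(diff(g) <= 0)) stop("recovered saturation curve is not strictly increasing")
  structure(list(g_grid = g, F_values = f_grid, interpolation = "linear",
                 assumed_true_sd = s),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("<saturation_curve> %d grid points, F range [%.4g, %.4g], g range [%.4g, %.4g]\n",
              length(x$g_grid), min(x$F_values), max(x$F_values),
              min(x$g_grid), max(x$g_grid)))
  invisible(x)
}

#' Evaluate or invert a tabulated saturation curve
#'
#' `sat_apply` maps true signal to observed signal, `sat_invert` maps
#' observed back to true (the linearization), both by monotone piecewise
#' linear interpolation of the tabulated curve.
#'
#' @param sat a [saturation_curve][build_saturation_curve].
#' @param g,v numeric vectors of true and observed values.
#' @return Numeric vector.
#' @export
sat_apply <- function(sat, g) {
  approx(sat$g_grid, sat$F_values, xout = g, rule = 2)$y
}

#' @rdname sat_apply
#' @export
sat_invert <- function(sat, v) {
  approx(sat$F_values, sat$g_grid, xout = v, rule = 2)$y
}

#' Linearize a replicate set through the inverse saturation map
#'
#' Every replicate value `v` is replaced by `F^-1(v)`.  Values outside the
#' tabulated range are clamped to the range ends with a warning.
#'
#' @param data a [replicate_set].
#' @param sat a [saturation_curve][build_saturation_curve].
#'
#' @return A linearized [replicate_set].
#' @export
linearize <- function(data, sat) {
  stopifnot(inherits(data, "replicate_set"), inherits(sat, "saturation_curve"))
  if (any(diff(sat$F_values) <= 0) || any(diff(sat$g_grid) <= 0))
    stop("saturation curve tabulation is not strictly increasing")
  rng <- range(sat$F_values)
  all_v <- c(data$values, data$control_values)
  n_out <- sum(all_v < rng[1L] | all_v > rng[2L], na.rm = TRUE)
  if (n_out > 0L)
    warning(sprintf("%d values outside the tabulated range were clamped", n_out))
  v <- data$values
  v[] <- sat_invert(sat, as.vector(v))
  cv <- data$control_values
  cv[] <- sat_invert(sat, as.vector(cv))
  replicate_set(v, cv, gene_ids = data$gene_ids,
                stimulus_ids = data$stimulus_ids)
}

#' Write or read a tabulated curve as a two-column TSV
#'
#' @param curve a `noise_curve` or `saturation_curve`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  if (inherits(curve, "noise_curve")) {
    df <- data.frame(mean_expression = curve$bin_mean_expression,
                     sd = curve$bin_sd,
                     n_pairs = curve$n_pairs_per_bin)
  } else if (inherits(curve, "saturation_curve")) {
    df <- data.frame(g = curve$g_grid, F = curve$F_values)
  } else stop("unsupported curve class")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
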