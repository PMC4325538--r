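#' Shannon entropy of a binary on/off profile
#'
#' `H = -sum_{c in {0,1}} p(c) log2 p(c)` with empirical state probabilities
#' and the convention `0 * log 0 = 0`.  A gene on in 13 of 26 stimuli has
#' `p(on) = 0.5` and entropy 1 bit.
#'
#' @param x logical vector of on/off states over stimuli.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x) {
  x <- check_binary(x)
  p <- mean(x)
  plogp(p) + plogp(1 - p)
}

#' Joint entropy of a pair of binary profiles
#'
#' Base-2 entropy of the empirical 2x2 joint distribution of the aligned
#' profiles.
#'
#' @param x,y logical vectors of equal length over the same stimuli.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(x, y) {
  x <- check_binary(x); y <- check_binary(y)
  if (length(x) != length(y)) stop("profiles have different lengths")
  n <- length(x)
  n11 <- sum(x & y)
  tab <- c(n11, sum(x) - n11, sum(y) - n11, n - sum(x) - sum(y) + n11) / n
  sum(vapply(tab, plogp, 0))
}

#' Mutual information between two binary profiles
#'
#' `I(x, y) = H(x) + H(y) - H(x, y)` in bits, clipped at zero against
#' roundoff.  MI is symmetric and invariant under complementing either
#' profile, so anticorrelated pairs carry as much information as correlated
#' ones.
#'
#' @param x,y logical vectors of equal length over the same stimuli.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  max(shannon_entropy(x) + shannon_entropy(y) - joint_entropy(x, y), 0)
}

check_binary <- function(x) {
  if (length(x) < 1L) stop("empty profile")
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("profile must be binary")
    x <- x > 0
  }
  if (!is.logical(x) || anyNA(x)) stop("profile must be logical without NA")
  x
}

plogp <- function(p) if (p <= 0) 0 else -p * log2(p)

# MI in bits from joint count n11 and margins, vectorized over n11;
# used on permutation draws where only the joint count varies
mi_from_counts <- function(n11, n1, n2, n) {
  n10 <- n1 - n11; n01 <- n2 - n11; n00 <- n - n1 - n2 + n11
  term <- function(nij, ni, nj) {
    out <- numeric(length(n11))
    pos <- nij > 0
    out[pos] <- nij[pos] / n * log2(n * nij[pos] / (ni[pos] * nj[pos]))
    out
  }
  r1 <- rep_len(n1, length(n11)); r0 <- n - r1
  c1 <- rep_len(n2, length(n11)); c0 <- n - c1
  pmax(term(n11, r1, c1) + term(n10, r1, c0) +
       term(n01, r0, c1) + term(n00, r0, c0), 0)
}

#' Permutation significance of the mutual information of a profile pair
#'
#' The second profile's stimulus order is permuted `n_perm` times and the MI
#' recomputed.  The default p-value uses the add-one convention
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm)`, which is always positive
#' and valid but conservative for a discrete statistic;
#' `tie_break = "randomized"` breaks ties at the observed value uniformly at
#' random, giving p-values that are exactly uniform under the null (useful
#' for calibration checks).
#'
#' @param x,y logical vectors of equal length (>= 2) over shared stimuli.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param tie_break `"conservative"` (default, add-one) or `"randomized"`.
#'
#' @return An object of class `mi_result` with entropies, MI, the Pearson
#'   correlation of the binary vectors (the sign information MI discards),
#'   the permutation p-value and bookkeeping.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000L, seed = NULL,
                               tie_break = c("conservative", "randomized")) {
  tie_break <- match.arg(tie_break)
  x <- check_binary(x); y <- check_binary(y)
  if (length(x) != length(y)) stop("profiles have different lengths")
  if (length(x) < 2L) stop("need at least two stimuli")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)

  n <- length(x); n1 <- sum(x); n2 <- sum(y)
  i_obs <- mutual_information(x, y)
  # permuting y leaves both margins fixed: only the joint count varies
  n11_perm <- vapply(seq_len(n_perm),
                     function(i) sum(x & y[sample.int(n)]), 0L)
  i_perm <- mi_from_counts(n11_perm, n1, n2, n)
  p <- if (tie_break == "conservative") {
    (1 + sum(i_perm >= i_obs - 1e-12)) / (1 + n_perm)
  } else {
    n_gt <- sum(i_perm > i_obs + 1e-12)
    n_eq <- sum(abs(i_perm - i_obs) <= 1e-12)
    (n_gt + runif(1) * (1 + n_eq)) / (1 + n_perm)
  }
  rho <- if (n1 %in% c(0L, n) || n2 %in% c(0L, n)) NA_real_ else cor(x, y)
  structure(list(h_x = shannon_entropy(x), h_y = shannon_entropy(y),
                 h_joint = joint_entropy(x, y), mi = i_obs, pearson = rho,
                 p_value = p, n_permutations = as.integer(n_perm),
                 seed = seed, tie_break = tie_break),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> MI %.4f bits (H %.3f/%.3f), rho %s, p = %.4g (%d perms)\n",
              x$mi, x$h_x, x$h_y,
              ifelse(is.na(x$pearson), "NA", sprintf("%.3f", x$pearson)),
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Screen all mapped ortholog pairs for mutual information
#'
#' Computes an [mi_result][permutation_pvalue] for every pair in the
#' ortholog map (with multiplicity, as many-to-many mappings are kept) and
#' ranks pairs by MI.  A whole-dataset permutation null histogram is also
#' returned: the stimuli of the second matrix are permuted `n_null` times,
#' the MI of every pair recomputed, and the per-bin mean and SD of the
#' counts recorded.
#'
#' @param a,b [activation_matrix] objects for the two species, sharing the
#'   stimulus set (columns aligned).
#' @param map an [ortholog_map]; `NULL` means identity mapping on shared row
#'   names.
#' @param n_perm permutations per pair for the p-value.
#' @param seed integer seed.
#' @param n_null whole-dataset permutations for the null histogram.
#' @param mi_breaks histogram bin edges in bits.
#'
#' @return A list with `table` (a data.frame with columns `id_a`, `id_b`,
#'   `mi_bits`, `pearson`, `p_value`, ranked by MI descending) and
#'   `null_histogram` (`breaks`, observed `counts`, per-bin `null_mean` and
#'   `null_sd` across permuted datasets).
#' @export
pairwise_mi_screen <- function(a, b, map = NULL, n_perm = 1000L, seed = 1L,
                               n_null = 100L,
                               mi_breaks = seq(0, 1, by = 0.025)) {
  stopifnot(inherits(a, "activation_matrix"), inherits(b, "activation_matrix"))
  if (ncol(a$on) != ncol(b$on))
    stop("activation matrices must share the stimulus set")
  if (is.null(map)) {
    shared <- intersect(rownames(a$on), rownames(b$on))
    map <- ortholog_map(data.frame(id_a = shared, id_b = shared))
  }
  bad_a <- setdiff(map$pairs$id_a, rownames(a$on))
  bad_b <- setdiff(map$pairs$id_b, rownames(b$on))
  if (length(bad_a) || length(bad_b))
    stop("unmapped identifiers: ",
         paste(head(c(bad_a, bad_b), 10L), collapse = ", "))
  set.seed(seed)

  ia <- match(map$pairs$id_a, rownames(a$on))
  ib <- match(map$pairs$id_b, rownames(b$on))
  res <- lapply(seq_len(nrow(map$pairs)), function(i) {
    r <- permutation_pvalue(a$on[ia[i], ], b$on[ib[i], ], n_perm = n_perm)
    c(mi = r$mi, pearson = r$pearson, p_value = r$p_value)
  })
  res <- do.call(rbind, res)
  tab <- data.frame(id_a = map$pairs$id_a, id_b = map$pairs$id_b,
                    mi_bits = res[, "mi"], pearson = res[, "pearson"],
                    p_value = res[, "p_value"], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mi_bits), ]
  rownames(tab) <- NULL

  n_stim <- ncol(a$on)
  obs_counts <- hist_counts(tab$mi_bits, mi_breaks)
  null_counts <- vapply(seq_len(n_null), function(i) {
    perm <- sample.int(n_stim)
    mi <- vapply(seq_len(nrow(map$pairs)), function(j)
      mutual_information(a$on[ia[j], ], b$on[ib[j], perm]), 0)
    hist_counts(mi, mi_breaks)
  }, numeric(length(mi_breaks) - 1L))
  list(table = tab,
       null_histogram = list(breaks = mi_breaks, counts = obs_counts,
                             null_mean = rowMeans(null_counts),
                             null_sd = apply(null_counts, 1L, sd),
                             n_null = as.integer(n_null)))
}

hist_counts <- function(x, breaks) {
  x <- pmin(pmax(x, breaks[1L]), breaks[length(breaks)])
  tabulate(findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE),
           nbins = length(breaks) - 1L)
}

#' Write a ranked MI table as TSV
#'
#' @param screen result of [pairwise_mi_screen()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_mi_table <- function(screen, path) {
  write.table(screen$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
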