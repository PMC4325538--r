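#' Configuration for the synthetic replicate-expression generator
#'
#' Describes the generative world the noise-modelling pipeline assumes: true
#' signals drawn log-uniformly over a dynamic range, additive Gaussian
#' measurement noise with a constant (mean-independent) standard deviation in
#' true-signal space, a monotone concave saturation nonlinearity applied to
#' the noisy signal, and sporadic outliers displaced far from the replicate
#' mean.
#'
#' @param n_genes,n_stimuli number of genes and stimuli.
#' @param n_replicates replicates per treated (gene, stimulus) pair;
#'   must be at least 2.
#' @param n_control_replicates replicates for the single shared control.
#' @param signal_range two-element range of true signal; true signals are
#'   drawn log-uniformly over it so every noise-curve bin is populated.
#' @param true_noise_sd constant measurement noise SD in true-signal units.
#' @param saturation list describing the observed-vs-true map `F`:
#'   `list(type = "tanh", fmax = ...)` for the bounded concave default
#'   `F(g) = fmax * tanh(g / fmax)`, or `list(type = "identity")`.
#' @param outlier_rate fraction of replicate values replaced by outliers.
#' @param outlier_magnitude displacement of injected outliers, in multiples
#'   of the local observed SD (must exceed 3 for a 3-SD rule to see them).
#' @param de_fraction fraction of (gene, stimulus) pairs with a true shift
#'   versus control.
#' @param de_effect_size size of the true shift, in true-signal units
#'   (sign randomized per pair).
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return A validated list of class `synth_expression_config`.
#' @export
synth_expression_config <- function(n_genes = 2000L, n_stimuli = 26L,
                                    n_replicates = 3L,
                                    n_control_replicates = 5L,
                                    signal_range = c(20, 1000),
                                    true_noise_sd = 10,
                                    saturation = list(type = "tanh", fmax = 600),
                                    outlier_rate = 0.01,
                                    outlier_magnitude = 6,
                                    de_fraction = 0.1,
                                    de_effect_size = 50,
                                    seed = 1L) {
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2: downstream calls need >= 2 surviving replicates")
  if (n_control_replicates < 2L) stop("n_control_replicates must be >= 2")
  if (true_noise_sd <= 0) stop("true_noise_sd must be positive")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0, 1)")
  if (outlier_rate > 0 && outlier_magnitude <= 3)
    stop("outlier_magnitude must exceed 3 SD to be detectable by the 3-SD rule")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (signal_range[1L] <= 0 || diff(signal_range) <= 0)
    stop("signal_range must be a positive increasing interval")
  if (!saturation$type %in% c("tanh", "identity"))
    stop("unknown saturation type: ", saturation$type)
  structure(list(n_genes = as.integer(n_genes),
                 n_stimuli = as.integer(n_stimuli),
                 n_replicates = as.integer(n_replicates),
                 n_control_replicates = as.integer(n_control_replicates),
                 signal_range = signal_range,
                 true_noise_sd = true_noise_sd,
                 saturation = saturation,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 de_fraction = de_fraction,
                 de_effect_size = de_effect_size,
                 seed = as.integer(seed)),
            class = "synth_expression_config")
}

# Expected universal noise curve of a config, by quadrature: observed SD
# s * F'(g) averaged within 14 equal-count bins of the observed mean under
# the log-uniform signal law, returned as an interpolator over observed
# means (piecewise linear, constant beyond the end bins) mirroring
# interpolate_sd().
expected_binned_sd <- function(config, n_bins = 14L, n_quad = 4096L) {
  sat <- saturation_fun(config$saturation)
  lr <- log(config$signal_range)
  g <- exp(seq(lr[1L], lr[2L], length.out = n_quad))  # log-uniform quantiles
  f <- sat$F(g)
  sd_pt <- config$true_noise_sd * sat$dF(g)
  bin <- findInterval(seq_len(n_quad) - 1L, seq(0, n_quad, length.out = n_bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  bm <- vapply(seq_len(n_bins), function(b) mean(f[bin == b]), 0)
  bs <- vapply(seq_len(n_bins), function(b) mean(sd_pt[bin == b]), 0)
  function(x) approx(bm, bs, xout = x, rule = 2)$y
}

saturation_fun <- function(saturation) {
  switch(saturation$type,
         identity = list(F = identity, dF = function(g) rep(1, length(g))),
         tanh = {
           fmax <- saturation$fmax
           list(F = function(g) fmax * tanh(g / fmax),
                dF = function(g) 1 / cosh(g / fmax)^2)
         })
}

#' Generate synthetic replicate expression data
#'
#' Draws true signals, adds constant-SD Gaussian noise in true space, applies
#' the saturation map, and injects outliers by replacing a random subset of
#' replicate values with values displaced away from the pair mean by
#' `outlier_magnitude` local observed SDs (random sign).  A fraction
#' `de_fraction` of (gene, stimulus) pairs receives a true shift relative to
#' the shared control.
#'
#' @param config a [synth_expression_config()].
#'
#' @return A list with elements `data` (a [replicate_set]) and `truth`, a
#'   record of the generative state: true treated/control signals, the DE
#'   indicator matrix, outlier positions in both tensors, and the saturation
#'   map used.
#' @export
generate_replicate_expression <- function(config) {
  stopifnot(inherits(config, "synth_expression_config"))
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_stimuli
  nr <- config$n_replicates; nc <- config$n_control_replicates
  s <- config$true_noise_sd
  sat <- saturation_fun(config$saturation)

  # baseline true signal per gene, log-uniform over the dynamic range
  lr <- log(config$signal_range)
  g_base <- exp(runif(ng, lr[1L], lr[2L]))

  de <- matrix(runif(ng * ns) < config$de_fraction, ng, ns)
  de_sign <- matrix(sample(c(-1, 1), ng * ns, replace = TRUE), ng, ns)
  g_true <- matrix(g_base, ng, ns) + de * de_sign * config$de_effect_size

  noise <- array(rnorm(ng * ns * nr, sd = s), dim = c(ng, ns, nr))
  obs <- sat$F(as.vector(g_true)[rep(seq_len(ng * ns), nr)] + as.vector(noise))
  obs <- array(obs, dim = c(ng, ns, nr))

  cnoise <- matrix(rnorm(ng * nc, sd = s), ng, nc)
  cobs <- sat$F(matrix(g_base, ng, nc) + cnoise)

  # outliers: displace from the saturated pair mean by m local observed SDs.
  # "local observed SD" is the noise level as the pipeline's own universal
  # curve convention measures it (the expected equal-count binned curve, not
  # the pointwise s * F'(g)): binning smooths a steeply falling noise curve,
  # and a displacement calibrated against the smoothed curve is what
  # guarantees detectability by a k-SD rule applied to that curve.
  local_sd_of <- expected_binned_sd(config)
  out_t <- array(runif(ng * ns * nr) < config$outlier_rate, dim = c(ng, ns, nr))
  out_c <- matrix(runif(ng * nc) < config$outlier_rate, ng, nc)
  # the displacement strictly exceeds magnitude x SD (exponential excess,
  # emulating heavy-tailed corruption), sign random
  if (any(out_t)) {
    idx <- which(out_t)
    pair <- (idx - 1L) %% (ng * ns) + 1L
    f_mean <- sat$F(as.vector(g_true))[pair]
    obs[idx] <- f_mean + sample(c(-1, 1), length(idx), replace = TRUE) *
      (config$outlier_magnitude + stats::rexp(length(idx))) *
      local_sd_of(f_mean)
  }
  if (any(out_c)) {
    idx <- which(out_c)
    gene <- (idx - 1L) %% ng + 1L
    f_mean <- sat$F(g_base)[gene]
    cobs[idx] <- f_mean + sample(c(-1, 1), length(idx), replace = TRUE) *
      (config$outlier_magnitude + stats::rexp(length(idx))) *
      local_sd_of(f_mean)
  }

  gene_ids <- sprintf("g%05d", seq_len(ng))
  stim_ids <- sprintf("stim%02d", seq_len(ns))
  data <- replicate_set(obs, cobs, gene_ids = gene_ids, stimulus_ids = stim_ids)
  truth <- list(true_treated = g_true, true_control = g_base, de = de,
                outliers_treated = out_t, outliers_control = out_c,
                saturation = config$saturation, true_noise_sd = s,
                config = config)
  list(data = data, truth = truth)
}

#' Configuration for the synthetic cross-species translation generator
#'
#' Describes paired-species gene-set data with low-rank structure: a rat NES
#' matrix generated from `latent_rank` shared factors plus noise, and human
#' on/off labels obtained by thresholding the same factor combination per
#' gene set, complemented for an anticorrelated fraction and flipped with a
#' small label noise.  Marginal activation rates of the two species are
#' independent knobs so the observed rat:human ON imbalance can be emulated.
#'
#' @param n_genesets number of gene sets.
#' @param n_train_stimuli,n_test_stimuli stimuli with known human labels
#'   (set A) and held-out stimuli (set B).
#' @param latent_rank number k of shared latent factors (< n_genesets).
#' @param nes_noise_sd SD of the additive noise on the rat NES matrix, on
#'   top of unit-variance factors.
#' @param human_label_noise probability of flipping a human label, in
#'   \[0, 0.5).
#' @param frac_anticorrelated fraction of gene sets whose human labels are
#'   the complement of the latent rule.
#' @param rat_activation_rate,human_activation_rate marginal on-rates; the
#'   defaults encode a roughly 3:1 rat:human imbalance.
#' @param seed integer seed.
#'
#' @return A validated list of class `synth_translation_config`.
#' @export
synth_translation_config <- function(n_genesets = 246L,
                                     n_train_stimuli = 26L,
                                     n_test_stimuli = 26L,
                                     latent_rank = 8L,
                                     nes_noise_sd = 0.5,
                                     human_label_noise = 0.05,
                                     frac_anticorrelated = 0.1,
                                     rat_activation_rate = 0.45,
                                     human_activation_rate = 0.15,
                                     seed = 1L) {
  if (latent_rank >= n_genesets) stop("latent_rank must be < n_genesets")
  if (latent_rank < 1L) stop("latent_rank must be >= 1")
  if (human_label_noise < 0 || human_label_noise >= 0.5)
    stop("human_label_noise must be in [0, 0.5)")
  if (frac_anticorrelated < 0 || frac_anticorrelated > 1)
    stop("frac_anticorrelated must be in [0, 1]")
  for (r in c(rat_activation_rate, human_activation_rate))
    if (r <= 0 || r >= 1) stop("activation rates must be in (0, 1)")
  structure(list(n_genesets = as.integer(n_genesets),
                 n_train_stimuli = as.integer(n_train_stimuli),
                 n_test_stimuli = as.integer(n_test_stimuli),
                 latent_rank = as.integer(latent_rank),
                 nes_noise_sd = nes_noise_sd,
                 human_label_noise = human_label_noise,
                 frac_anticorrelated = frac_anticorrelated,
                 rat_activation_rate = rat_activation_rate,
                 human_activation_rate = human_activation_rate,
                 seed = as.integer(seed)),
            class = "synth_translation_config")
}

# fdr values consistent with binary labels under a strict fdr < 0.25 rule:
# on -> uniform [0, 0.25), off -> uniform [0.25, 1]
fdr_from_labels <- function(on) {
  f <- matrix(NA_real_, nrow(on), ncol(on), dimnames = dimnames(on))
  n_on <- sum(on); n_off <- sum(!on)
  f[on] <- runif(n_on, 0, 0.25 - 1e-9)
  f[!on] <- runif(n_off, 0.25, 1)
  f
}

#' Generate a synthetic cross-species translation dataset
#'
#' @param config a [synth_translation_config()].
#'
#' @return A list with:
#'   \describe{
#'     \item{rat_nes}{[geneset_scores] over all train+test stimuli (rat FDR
#'       attached, consistent with the thresholded rat activations).}
#'     \item{human_a}{[geneset_scores] for the training stimuli (human FDR
#'       consistent with the training labels).}
#'     \item{human_b_gold}{[activation_matrix] of gold-standard human labels
#'       on the test stimuli.}
#'     \item{rat_activation}{[activation_matrix] of thresholded rat calls.}
#'     \item{geneset_membership}{named list of synthetic member genes per
#'       set, writable with [write_gmt()].}
#'     \item{map}{identity [ortholog_map] over gene-set ids.}
#'     \item{train_stimuli, test_stimuli}{stimulus id vectors.}
#'     \item{truth}{factors, loadings, clean labels, flip and anticorrelated
#'       indicators.}
#'   }
#' @export
generate_translation_dataset <- function(config) {
  stopifnot(inherits(config, "synth_translation_config"))
  set.seed(config$seed)
  p <- config$n_genesets
  n_a <- config$n_train_stimuli; n_b <- config$n_test_stimuli
  n <- n_a + n_b
  k <- config$latent_rank

  set_ids <- sprintf("GS%04d", seq_len(p))
  stim_ids <- sprintf("stim%02d", seq_len(n))
  train_ids <- stim_ids[seq_len(n_a)]
  test_ids <- stim_ids[n_a + seq_len(n_b)]

  loadings <- matrix(rnorm(p * k), p, k)
  factors <- matrix(rnorm(k * n), k, n)
  signal <- loadings %*% factors                       # p x n
  nes <- signal + matrix(rnorm(p * n, sd = config$nes_noise_sd), p, n)
  dimnames(nes) <- list(set_ids, stim_ids)

  # human labels: per-set threshold on the clean factor combination so the
  # marginal on-rate is human_activation_rate; complement the anticorrelated
  # fraction; then flip with probability human_label_noise
  thr <- apply(signal, 1L, quantile, probs = 1 - config$human_activation_rate)
  labels_clean <- sweep(signal, 1L, thr, `>`)
  anti <- runif(p) < config$frac_anticorrelated
  labels_clean[anti, ] <- !labels_clean[anti, ]
  flips <- matrix(runif(p * n) < config$human_label_noise, p, n)
  labels <- xor(labels_clean, flips)
  dimnames(labels) <- list(set_ids, stim_ids)

  # rat activations: per-set threshold on the noisy NES at the rat on-rate
  rthr <- apply(nes, 1L, quantile, probs = 1 - config$rat_activation_rate)
  rat_on <- sweep(nes, 1L, rthr, `>`)

  dimnames(signal) <- dimnames(rat_on) <- list(set_ids, stim_ids)
  rat_fdr <- fdr_from_labels(rat_on)
  human_fdr_a <- fdr_from_labels(labels[, train_ids, drop = FALSE])
  human_nes_a <- signal[, train_ids, drop = FALSE] +
    matrix(rnorm(p * n_a, sd = config$nes_noise_sd), p, n_a)
  dimnames(human_nes_a) <- list(set_ids, train_ids)

  # synthetic gene-set membership (for the GMT writer); sizes log-uniform
  # between 15 and 200 genes over a shared synthetic gene universe
  sizes <- pmax(15L, round(exp(runif(p, log(15), log(200)))))
  membership <- lapply(sizes, function(k) sprintf("gene%05d", sample.int(20000L, k)))
  names(membership) <- set_ids

  list(rat_nes = geneset_scores(nes, rat_fdr, species = "rat"),
       geneset_membership = membership,
       human_a = geneset_scores(human_nes_a, human_fdr_a, species = "human"),
       human_b_gold = activation_matrix(labels[, test_ids, drop = FALSE],
                                        source = "gene set", threshold = 0.25),
       rat_activation = activation_matrix(rat_on, source = "gene set",
                                          threshold = 0.25),
       map = ortholog_map(data.frame(id_a = set_ids, id_b = set_ids)),
       train_stimuli = train_ids, test_stimuli = test_ids,
       truth = list(loadings = loadings, factors = factors,
                    labels_clean = labels_clean, labels = labels,
                    anticorrelated = anti, flips = flips, config = config))
}
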