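#' Pipeline configuration
#'
#' A single flat configuration driving an end-to-end run
#' (generate -> noise -> calls -> mi -> translate -> score).  Any input that
#' is supplied precomputed short-circuits the stages that would produce it:
#' with `generate = FALSE` and NES/FDR paths given, the expression stages are
#' skipped, matching a run on real challenge-style matrices.
#'
#' @param out_dir output directory (created if absent).
#' @param generate generate synthetic inputs into `out_dir` first.
#' @param expression_config,translation_config generator configurations
#'   (defaults used when `NULL`); their seeds are re-derived from `seed`.
#' @param treated_tsv,control_tsv long-format expression tables (optional;
#'   enable the noise/diffexpr stages).
#' @param rat_nes_tsv,rat_fdr_tsv rat gene-set score matrices over all
#'   stimuli (train + test).
#' @param human_fdr_tsv,human_nes_tsv human training (set A) matrices.
#' @param gold_tsv human gold-standard FDR matrix for the test stimuli
#'   (optional; enables the score stage).
#' @param ortholog_map_tsv two-column id map (optional; enables the mi
#'   stage, identity map used when absent and `run_mi` is TRUE).
#' @param train_stimuli,test_stimuli stimulus id vectors; when `NULL` they
#'   are taken from the human training matrix columns and the remaining rat
#'   columns respectively.
#' @param n_bins,k_sd,alpha,fdr_cut,n_components,n_perm,covariance module
#'   parameters (defaults 14, 3, 0.01, 0.25, 8, 1000, `"diagonal"`).
#' @param run_mi run the mutual-information screen (default TRUE).
#' @param seed integer master seed; per-stage substreams are derived from
#'   it.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, generate = FALSE,
                            expression_config = NULL,
                            translation_config = NULL,
                            treated_tsv = NULL, control_tsv = NULL,
                            rat_nes_tsv = NULL, rat_fdr_tsv = NULL,
                            human_fdr_tsv = NULL, human_nes_tsv = NULL,
                            gold_tsv = NULL, ortholog_map_tsv = NULL,
                            train_stimuli = NULL, test_stimuli = NULL,
                            n_bins = 14L, k_sd = 3, alpha = 0.01,
                            fdr_cut = 0.25, n_components = 8L,
                            n_perm = 1000L,
                            covariance = c("diagonal", "full"),
                            run_mi = TRUE, seed = 1L) {
  covariance <- match.arg(covariance)
  cfg <- list(out_dir = out_dir, generate = generate,
              expression_config = expression_config,
              translation_config = translation_config,
              treated_tsv = treated_tsv, control_tsv = control_tsv,
              rat_nes_tsv = rat_nes_tsv, rat_fdr_tsv = rat_fdr_tsv,
              human_fdr_tsv = human_fdr_tsv, human_nes_tsv = human_nes_tsv,
              gold_tsv = gold_tsv, ortholog_map_tsv = ortholog_map_tsv,
              train_stimuli = train_stimuli, test_stimuli = test_stimuli,
              n_bins = as.integer(n_bins), k_sd = k_sd, alpha = alpha,
              fdr_cut = fdr_cut, n_components = as.integer(n_components),
              n_perm = as.integer(n_perm), covariance = covariance,
              run_mi = run_mi, seed = as.integer(seed))
  if (!generate) {
    paths <- unlist(cfg[c("treated_tsv", "control_tsv", "rat_nes_tsv",
                          "rat_fdr_tsv", "human_fdr_tsv", "human_nes_tsv",
                          "gold_tsv", "ortholog_map_tsv")])
    missing <- paths[!vapply(paths, file.exists, TRUE)]
    if (length(missing))
      stop("referenced inputs do not exist: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

# deterministic per-stage substream seeds below 2^31
stage_seed <- function(seed, stage) {
  (seed * 1009L + match(stage, c("generate", "noise", "calls", "mi",
                                 "translate", "score")) * 7919L) %% 2147483647L
}

#' Run the full pipeline from one configuration
#'
#' Executes the stages in dependency order, skipping stages whose inputs are
#' supplied precomputed, and writes every stage output plus a run manifest
#' (config snapshot, package version, per-output checksums, timestamps) to
#' `config$out_dir`.  Deterministic under the configured seed: re-running an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#'
#' @return The run manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[genesettr] ", sprintf(...))
  out <- function(f) file.path(config$out_dir, f)
  outputs <- character()
  stages_run <- character()
  t0 <- Sys.time()

  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  ## ---- stage: generate -------------------------------------------------
  if (config$generate) {
    stages_run <- c(stages_run, "generate")
    tryCatch({
      say("generate: synthesizing inputs (seed %d)", config$seed)
      ec <- config$expression_config %||%
        synth_expression_config(seed = stage_seed(config$seed, "generate"))
      tc <- config$translation_config %||%
        synth_translation_config(seed = stage_seed(config$seed, "generate"))
      gen <- generate_replicate_expression(ec)
      write_expression_tsv(gen$data, out("expression_treated.tsv"),
                           out("expression_control.tsv"))
      tr <- generate_translation_dataset(tc)
      write_matrix_tsv(tr$rat_nes$nes, out("rat_nes.tsv"), "gene_set")
      write_matrix_tsv(tr$rat_nes$fdr, out("rat_fdr.tsv"), "gene_set")
      write_matrix_tsv(tr$human_a$fdr, out("human_a_fdr.tsv"), "gene_set")
      write_matrix_tsv(tr$human_a$nes, out("human_a_nes.tsv"), "gene_set")
      write_matrix_tsv(fdr_from_labels(tr$human_b_gold$on),
                       out("human_b_gold_fdr.tsv"), "gene_set")
      write_ortholog_map(tr$map, out("ortholog_map.tsv"))
      write_gmt(tr$geneset_membership, out("genesets.gmt"))
      config$treated_tsv <- out("expression_treated.tsv")
      config$control_tsv <- out("expression_control.tsv")
      config$rat_nes_tsv <- out("rat_nes.tsv")
      config$rat_fdr_tsv <- out("rat_fdr.tsv")
      config$human_fdr_tsv <- out("human_a_fdr.tsv")
      config$human_nes_tsv <- out("human_a_nes.tsv")
      config$gold_tsv <- out("human_b_gold_fdr.tsv")
      config$ortholog_map_tsv <- out("ortholog_map.tsv")
      config$train_stimuli <- tr$train_stimuli
      config$test_stimuli <- tr$test_stimuli
      outputs <- c(outputs, out(c("expression_treated.tsv",
                                  "expression_control.tsv", "rat_nes.tsv",
                                  "rat_fdr.tsv", "human_a_fdr.tsv",
                                  "human_a_nes.tsv", "human_b_gold_fdr.tsv",
                                  "ortholog_map.tsv", "genesets.gmt")))
    }, error = function(e) fail("generate", e))
  }

  ## ---- stage: noise ----------------------------------------------------
  gene_activation <- NULL
  if (!is.null(config$treated_tsv)) {
    stages_run <- c(stages_run, "noise")
    tryCatch({
      say("noise: universal curve, outlier removal, linearization")
      expr <- read_expression_tsv(config$treated_tsv, config$control_tsv)
      curve_raw <- build_noise_curve(expr, n_bins = config$n_bins)
      cleaned <- remove_outliers(expr, curve_raw, k_sd = config$k_sd)
      sat <- build_saturation_curve(curve_raw)
      lin <- linearize(cleaned$data, sat)
      write_curve_tsv(curve_raw, out("noise_curve.tsv"))
      write_curve_tsv(sat, out("saturation_curve.tsv"))
      outputs <- c(outputs, out(c("noise_curve.tsv", "saturation_curve.tsv")))

      say("calls: differential expression at alpha %g", config$alpha)
      stages_run <- c(stages_run, "calls")
      curve_lin <- build_noise_curve(lin, n_bins = config$n_bins)
      de <- call_differential_genes(lin, curve_lin, alpha = config$alpha)
      write_matrix_tsv(de$p_values, out("gene_p_values.tsv"), "gene")
      gene_activation <- calls_to_activation(de)
      write_matrix_tsv(gene_activation$on * 1, out("gene_activation.tsv"),
                       "gene")
      outputs <- c(outputs, out(c("gene_p_values.tsv", "gene_activation.tsv")))
    }, error = function(e) fail("noise", e))
  }

  ## ---- stage: geneset binarization + translate -------------------------
  report <- NULL
  if (!is.null(config$rat_nes_tsv)) {
    tryCatch({
      rat_nes <- read_matrix_tsv(config$rat_nes_tsv)
      rat <- geneset_scores(rat_nes,
                            if (!is.null(config$rat_fdr_tsv))
                              read_matrix_tsv(config$rat_fdr_tsv),
                            species = "rat")
      human_fdr <- read_matrix_tsv(config$human_fdr_tsv)
      human <- geneset_scores(
        if (!is.null(config$human_nes_tsv)) read_matrix_tsv(config$human_nes_tsv)
        else human_fdr * 0,
        human_fdr, species = "human")
      train <- config$train_stimuli %||% colnames(human_fdr)
      test <- config$test_stimuli %||% setdiff(colnames(rat_nes), train)

      stages_run <- c(stages_run, "binarize")
      human_act <- binarize_genesets(human, fdr_cut = config$fdr_cut)
      rat_act <- if (!is.null(rat$fdr)) binarize_genesets(rat, config$fdr_cut)

      if (config$run_mi && !is.null(rat_act)) {
        stages_run <- c(stages_run, "mi")
        say("mi: screening %d gene-set pairs", nrow(rat_nes))
        map <- if (!is.null(config$ortholog_map_tsv))
          read_ortholog_map(config$ortholog_map_tsv)
        rat_a <- activation_matrix(rat_act$on[, train, drop = FALSE],
                                   "gene set", config$fdr_cut)
        screen <- pairwise_mi_screen(rat_a, human_act, map,
                                     n_perm = config$n_perm,
                                     seed = stage_seed(config$seed, "mi"))
        write_mi_table(screen, out("mi_ranked.tsv"))
        outputs <- c(outputs, out("mi_ranked.tsv"))
      }

      stages_run <- c(stages_run, "translate")
      say("translate: N = %d, %s covariance, %d folds", config$n_components,
          config$covariance, length(train))
      pca <- fit_pca(rat, config$n_components)
      pred <- predict_loo_ensemble(pca, human_act, train, test,
                                   n_components = config$n_components,
                                   covariance = config$covariance)
      write_matrix_tsv(pred$p_on, out("predictions.tsv"), "gene_set")
      outputs <- c(outputs, out("predictions.tsv"))

      if (!is.null(config$gold_tsv)) {
        stages_run <- c(stages_run, "score")
        gold_fdr <- read_matrix_tsv(config$gold_tsv)
        gold_scores <- geneset_scores(gold_fdr * 0, gold_fdr, "human")
        gold <- binarize_genesets(gold_scores, config$fdr_cut)
        report <- score_predictions(pred, gold, gold_scores)
        say("score: AUROC %.3f, AUPR %.3f, BAC %.3f", report$auroc,
            report$aupr, report$bac)
        writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                    digits = NA, na = "null"),
                   out("evaluation.json"))
        outputs <- c(outputs, out("evaluation.json"))
      }
    }, error = function(e) fail("translate", e))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("genesettr")),
    config = config[!vapply(config, is.null, TRUE) &
                    !names(config) %in% c("expression_config",
                                          "translation_config")],
    stages_run = stages_run,
    outputs = as.list(tools::md5sum(outputs)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    evaluation = if (!is.null(report)) unclass(report))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              na = "null", null = "null"),
             out("manifest.json"))
  invisible(manifest)
}

#' Parse a flat key:value pipeline configuration file
#'
#' One `key: value` pair per line; `#` starts a comment; comma-separated
#' values become vectors; numbers and TRUE/FALSE are coerced.  Keys mirror
#' the arguments of [pipeline_config()].
#'
#' @param path file path.
#' @param ... overrides applied after the file is read (flags win over file
#'   values).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines, fixed = TRUE)])
  kv <- regmatches(lines, regexpr(":", lines, fixed = TRUE), invert = TRUE)
  args <- stats::setNames(
    lapply(kv, function(p) coerce_value(trimws(p[2L]))),
    vapply(kv, function(p) trimws(p[1L]), ""))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

coerce_value <- function(v) {
  if (grepl(",", v, fixed = TRUE))
    return(unlist(lapply(trimws(strsplit(v, ",", fixed = TRUE)[[1L]]),
                         coerce_value), use.names = FALSE))
  if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}
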