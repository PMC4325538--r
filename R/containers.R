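#' Replicate expression set
#'
#' Container for a gene x stimulus x replicate expression tensor plus the
#' matched control replicates.  Missing replicate values are allowed (`NA`);
#' any (gene, stimulus) pair used downstream must retain at least two
#' non-missing replicates.
#'
#' @param values numeric 3-d array, dimensions gene x stimulus x replicate.
#' @param control_values numeric matrix, gene x control-replicate.
#' @param gene_ids,stimulus_ids character vectors naming the first two
#'   dimensions; defaults are taken from `dimnames(values)`.
#'
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(values, control_values,
                          gene_ids = NULL, stimulus_ids = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (gene x stimulus x replicate)")
  if (!is.matrix(control_values))
    stop("`control_values` must be a matrix (gene x replicate)")
  if (nrow(control_values) != dim(values)[1L])
    stop("control and treated matrices disagree on the number of genes")
  if (any(!is.finite(values) & !is.na(values)) ||
      any(!is.finite(control_values) & !is.na(control_values)))
    stop("expression values must be finite or NA")
  if (is.null(gene_ids))
    gene_ids <- dimnames(values)[[1L]] %||% sprintf("g%04d", seq_len(dim(values)[1L]))
  if (is.null(stimulus_ids))
    stimulus_ids <- dimnames(values)[[2L]] %||% sprintf("stim%02d", seq_len(dim(values)[2L]))
  dimnames(values) <- list(gene_ids, stimulus_ids, NULL)
  rownames(control_values) <- gene_ids
  structure(
    list(values = values, control_values = control_values,
         gene_ids = gene_ids, stimulus_ids = stimulus_ids),
    class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<replicate_set> %d genes x %d stimuli x %d replicates (+%d control replicates)\n",
    d[1L], d[2L], d[3L], ncol(x$control_values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0L) cat(sprintf("  %d missing replicate values\n", n_na))
  invisible(x)
}

#' Gene-set score matrix (NES + FDR)
#'
#' Holds the continuous normalized-enrichment-score signal and the matching
#' false-discovery-rate significance for one species, gene sets in rows and
#' stimuli in columns.
#'
#' @param nes numeric matrix of normalized enrichment scores.
#' @param fdr numeric matrix of FDR values in \[0, 1\], same shape as `nes`.
#' @param species character tag, e.g. `"rat"` or `"human"`.
#'
#' @return An object of class `geneset_scores`.
#' @export
geneset_scores <- function(nes, fdr = NULL, species = "unknown") {
  nes <- as.matrix(nes)
  if (!all(is.finite(nes))) stop("NES values must be finite")
  if (!is.null(fdr)) {
    fdr <- as.matrix(fdr)
    if (!identical(dim(fdr), dim(nes)))
      stop("`nes` and `fdr` must have identical dimensions")
    if (any(fdr < 0 | fdr > 1, na.rm = TRUE))
      stop("FDR values must lie in [0, 1]")
    dimnames(fdr) <- dimnames(nes)
  }
  structure(
    list(nes = nes, fdr = fdr, species = species,
         set_ids = rownames(nes), stimulus_ids = colnames(nes)),
    class = "geneset_scores")
}

#' @export
print.geneset_scores <- function(x, ...) {
  cat(sprintf("<geneset_scores:%s> %d gene sets x %d stimuli (fdr: %s)\n",
              x$species, nrow(x$nes), ncol(x$nes),
              if (is.null(x$fdr)) "absent" else "present"))
  invisible(x)
}

#' Binary activation matrix
#'
#' Item x stimulus on/off calls derived from a score matrix and a threshold.
#'
#' @param on logical matrix of activation calls (NA allowed for discarded
#'   items).
#' @param source `"gene"` or `"gene set"`.
#' @param threshold the threshold that produced the calls.
#'
#' @return An object of class `activation_matrix`.
#' @export
activation_matrix <- function(on, source = c("gene set", "gene"),
                              threshold = NA_real_) {
  source <- match.arg(source)
  on <- as.matrix(on)
  if (!is.logical(on)) stop("`on` must be a logical matrix")
  structure(list(on = on, source = source, threshold = threshold),
            class = "activation_matrix")
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("<activation_matrix> %d %ss x %d stimuli, %d on (threshold %s)\n",
              nrow(x$on), x$source, ncol(x$on), sum(x$on, na.rm = TRUE),
              format(x$threshold)))
  invisible(x)
}

#' Ortholog map
#'
#' Pair list linking identifiers in one species to identifiers in another.
#' Many-to-many mappings are allowed and every pair is kept with its
#' multiplicity.
#'
#' @param pairs two-column data.frame or matrix; column 1 holds species-1
#'   identifiers, column 2 species-2 identifiers.
#'
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("ortholog map needs two identifier columns")
  pairs <- data.frame(id_a = as.character(pairs[[1L]]),
                      id_b = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs), class = "ortholog_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
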