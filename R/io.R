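#' Read and write labelled matrices as TSV
#'
#' All tabular I/O in the package uses tab-separated text with a header row
#' and the row identifier in the first column.
#'
#' @param path file path.
#' @param x numeric matrix with row and column names.
#' @param id_name header for the identifier column.
#'
#' @return `read_matrix_tsv` returns a numeric matrix; `write_matrix_tsv`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write replicate expression data as long-format TSV
#'
#' The treated table has columns `gene`, `stimulus`, `replicate`, `value`;
#' the control table has columns `gene`, `replicate`, `value`.
#'
#' @param data a [replicate_set].
#' @param treated_path,control_path file paths for the two tables.
#'
#' @return `read_expression_tsv` returns a [replicate_set];
#'   `write_expression_tsv` returns the paths invisibly.
#' @export
write_expression_tsv <- function(data, treated_path, control_path) {
  v <- data$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  long <- data.frame(gene = data$gene_ids[idx[, 1L]],
                     stimulus = data$stimulus_ids[idx[, 2L]],
                     replicate = idx[, 3L],
                     value = v[idx],
                     stringsAsFactors = FALSE)
  write.table(long, treated_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cv <- data$control_values
  cidx <- which(!is.na(cv), arr.ind = TRUE)
  clong <- data.frame(gene = data$gene_ids[cidx[, 1L]],
                      replicate = cidx[, 2L],
                      value = cv[cidx],
                      stringsAsFactors = FALSE)
  write.table(clong, control_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(treated_path, control_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(treated_path, control_path) {
  long <- read.delim(treated_path, stringsAsFactors = FALSE)
  clong <- read.delim(control_path, stringsAsFactors = FALSE)
  genes <- sort(unique(c(long$gene, clong$gene)))
  stimuli <- unique(long$stimulus)
  n_rep <- max(long$replicate)
  v <- array(NA_real_, dim = c(length(genes), length(stimuli), n_rep),
             dimnames = list(genes, stimuli, NULL))
  v[cbind(match(long$gene, genes), match(long$stimulus, stimuli),
          long$replicate)] <- long$value
  cv <- matrix(NA_real_, length(genes), max(clong$replicate),
               dimnames = list(genes, NULL))
  cv[cbind(match(clong$gene, genes), clong$replicate)] <- clong$value
  replicate_set(v, cv, gene_ids = genes, stimulus_ids = stimuli)
}

#' Read and write gene-set definitions in GMT format
#'
#' One gene set per line: name, description, then tab-separated member gene
#' identifiers.
#'
#' @param path file path.
#' @param sets named list of character vectors (member genes per set).
#' @param descriptions optional character vector of set descriptions.
#'
#' @return `read_gmt` returns a named list of character vectors with the
#'   descriptions attached as an attribute; `write_gmt` returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog map from a two-column TSV
#'
#' @param path file path; the file must have a header row and at least two
#'   columns (species-1 id, species-2 id).
#'
#' @return An [ortholog_map].
#' @export
read_ortholog_map <- function(path) {
  ortholog_map(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_ortholog_map
#' @param map an [ortholog_map].
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
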