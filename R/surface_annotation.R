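# SPC (surface prediction consensus) scores are integers 0-4 supplied by an
# external table; 3-4 marks a high-confidence cell-surface prediction. A
# score of 0 is NOT evidence of intracellular localization (GPI-anchored and
# ECM proteins also score 0), so missing genes are marked, never coerced to 0.

#' Read an SPC score table
#'
#' @param path TSV with columns `gene_symbol` and `spc_score` (integers 0-4).
#' @return A named integer vector keyed by gene symbol.
#' @export
read_spc_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_symbol", "spc_score")
  if (!all(req %in% names(d))) {
    stop("SPC table needs columns: ", paste(req, collapse = ", "))
  }
  as_spc_table(setNames(as.integer(d$spc_score), d$gene_symbol))
}

as_spc_table <- function(scores) {
  stopifnot(!is.null(names(scores)))
  scores[] <- as.integer(scores)
  if (any(!is.na(scores) & !(scores %in% 0:4))) {
    stop("SPC scores must be integers in 0..4")
  }
  scores
}

#' Annotate genes with SPC surface-prediction scores
#'
#' Gene symbols are matched exactly first, then case-insensitively for the
#' remainder (mixed-source tables often disagree on capitalization).
#'
#' @param genes Character vector of gene symbols to annotate.
#' @param spc_table Named integer vector (gene -> score 0-4), e.g. from
#'   [read_spc_table()].
#' @param missing_policy What to do with genes absent from the table:
#'   `"mark"` (default) records `NA`, `"drop"` removes the rows.
#' @return A `data.frame` with columns `gene` and `spc_score` (`NA` =
#'   missing under the `"mark"` policy).
#' @export
annotate_spc <- function(genes, spc_table, missing_policy = c("mark", "drop")) {
  missing_policy <- match.arg(missing_policy)
  spc_table <- as_spc_table(spc_table)
  score <- spc_table[match(genes, names(spc_table))]
  miss <- is.na(score)
  if (any(miss)) {
    score[miss] <- spc_table[match(toupper(genes[miss]), toupper(names(spc_table)))]
  }
  out <- data.frame(gene = genes, spc_score = unname(score),
                    stringsAsFactors = FALSE)
  if (missing_policy == "drop") out <- out[!is.na(out$spc_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-confidence surface filter
#'
#' Retains genes whose SPC score meets the high-confidence surface
#' threshold (score >= 3 by default, i.e. scores 3 or 4). Genes with a
#' missing score are excluded: absence of a prediction is not treated as a
#' score of 0.
#'
#' @param annotated Output of [annotate_spc()].
#' @param threshold Minimum SPC score retained (default 3).
#' @return The filtered subset of `annotated`.
#' @export
high_confidence_filter <- function(annotated, threshold = 3) {
  stopifnot(is.data.frame(annotated), "spc_score" %in% names(annotated))
  out <- annotated[!is.na(annotated$spc_score) &
                     annotated$spc_score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a topology annotation table
#'
#' Topology (transmembrane domain counts, signal peptides) is consumed from
#' an external predictor's output, not computed here.
#'
#' @param path TSV with columns `protein_id`, `n_tm_domains`,
#'   `has_signal_peptide` and optionally `source`.
#' @return A `data.frame` with those columns.
#' @export
read_topology_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "n_tm_domains", "has_signal_peptide")
  if (!all(req %in% names(d))) {
    stop("topology table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(d$n_tm_domains < 0)) stop("n_tm_domains must be nonnegative")
  d$has_signal_peptide <- as.logical(d$has_signal_peptide)
  d
}
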