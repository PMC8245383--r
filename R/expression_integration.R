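# Transcript counts (gene x sample, with day/replicate metadata) and
# glycopeptide spectral counts (protein x day) are integrated two ways:
# volcano-style differential tables for day-vs-day comparisons under the
# joint thresholds p < 0.05 and |log2FC| > 4, and per-protein profiles
# normalized to each modality's maximum detection.

#' Volcano configuration
#'
#' Thresholds and numerical settings for [differential()] /
#' [volcano_table()]. Defaults are the study thresholds: raw p < 0.05
#' together with |log2 fold change| > 4, fold changes computed against the
#' earliest differentiation day.
#'
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param fc_threshold Absolute log2 fold-change threshold (default 4).
#' @param reference_day Baseline day for comparisons (default 15).
#' @param count_pseudocount Pseudocount added before log2 (default 1).
#' @param min_count_threshold Genes whose total raw count across all
#'   samples is below this floor are excluded before testing (default 10).
#' @param normalize `"none"` (raw counts, the default: fold changes stay on
#'   the count scale and are unaffected by composition shifts) or `"cpm"`
#'   (counts per million per sample, for libraries of unequal depth).
#' @return A list of class `"volcano_config"`.
#' @export
volcano_config <- function(p_threshold = 0.05, fc_threshold = 4,
                           reference_day = 15, count_pseudocount = 1,
                           min_count_threshold = 10,
                           normalize = c("none", "cpm")) {
  stopifnot(p_threshold > 0, fc_threshold > 0, count_pseudocount >= 0)
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 reference_day = reference_day,
                 count_pseudocount = count_pseudocount,
                 min_count_threshold = min_count_threshold,
                 normalize = match.arg(normalize)),
            class = "volcano_config")
}

check_count_input <- function(counts, meta) {
  stopifnot(is.matrix(counts) || is.data.frame(counts))
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  stopifnot(is.data.frame(meta), all(c("sample", "day") %in% names(meta)))
  if (!setequal(colnames(counts), meta$sample)) {
    stop("count matrix columns and metadata samples disagree")
  }
  counts[, match(meta$sample, colnames(counts)), drop = FALSE]
}

#' Average counts across replicates within each day
#'
#' @param counts Gene x sample matrix of nonnegative counts.
#' @param meta Sample metadata `data.frame` with columns `sample`, `day`
#'   (and typically `replicate`).
#' @return A gene x day matrix of arithmetic means; columns named by day,
#'   in increasing day order.
#' @export
average_replicates <- function(counts, meta) {
  counts <- check_count_input(counts, meta)
  days <- sort(unique(meta$day))
  out <- vapply(days, function(d) {
    cols <- which(meta$day == d)
    if (length(cols) == 0) stop("day ", d, " has no samples")
    rowMeans(counts[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), as.character(days)))
  out
}

#' Normalize a nonnegative profile to its maximum
#'
#' Divides a per-timepoint vector by its maximum so the profile lies in
#' [0, 1] with the maximum exactly 1. An all-zero profile (entity never
#' detected) is returned unchanged with `detected = FALSE`.
#'
#' @param x Nonnegative numeric vector (one entity across timepoints).
#' @return A list: `profile` (numeric in [0,1]) and `detected` (logical).
#' @examples
#' normalize_to_max(c(100, 200, 400))$profile  # 0.25 0.50 1.00
#' @export
normalize_to_max <- function(x) {
  if (any(x < 0)) stop("values must be nonnegative")
  m <- max(x)
  if (m == 0) return(list(profile = x, detected = FALSE))
  list(profile = x / m, detected = TRUE)
}

#' Differential abundance between two days
#'
#' For each gene passing the expression floor, computes
#' `log2fc = log2(mean(day) + c) - log2(mean(reference_day) + c)` on
#' (optionally CPM-normalized) counts and a two-sided Welch t-test on
#' `log2(count + c)` across replicates. No multiple-testing correction is
#' applied to the significance flag (the thresholds are on raw p), but a
#' Benjamini-Hochberg adjusted column is emitted alongside. Groups with
#' fewer than 2 replicates, or zero variance in both groups, yield a
#' missing p-value and `significant = FALSE`.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @param meta Sample metadata (`sample`, `day`, `replicate`).
#' @param day Day to compare.
#' @param reference_day Baseline day; defaults to the config's.
#' @param config A [volcano_config()].
#' @return A `data.frame`: `gene`, `day`, `reference_day`, `base_mean`,
#'   `log2fc`, `p_value`, `p_adj`, `significant`. Attribute `"method"`
#'   records the test and normalization used.
#' @export
differential <- function(counts, meta, day, reference_day = NULL,
                         config = volcano_config()) {
  counts <- check_count_input(counts, meta)
  if (is.null(reference_day)) reference_day <- config$reference_day
  if (!day %in% meta$day) stop("day ", day, " absent from metadata")
  if (!reference_day %in% meta$day) {
    stop("reference day ", reference_day, " absent from metadata")
  }
  keep <- rowSums(counts) >= config$min_count_threshold
  counts <- counts[keep, , drop = FALSE]
  norm <- counts
  if (config$normalize == "cpm") {
    libsize <- colSums(counts)
    libsize[libsize == 0] <- 1
    norm <- sweep(counts, 2, libsize, "/") * 1e6
  }
  c0 <- config$count_pseudocount
  gcols <- which(meta$day == day)
  rcols <- which(meta$day == reference_day)
  lg <- log2(norm[, gcols, drop = FALSE] + c0)
  lr <- log2(norm[, rcols, drop = FALSE] + c0)
  log2fc <- log2(rowMeans(norm[, gcols, drop = FALSE]) + c0) -
    log2(rowMeans(norm[, rcols, drop = FALSE]) + c0)
  p <- rep(NA_real_, nrow(norm))
  if (length(gcols) >= 2 && length(rcols) >= 2) {
    for (i in seq_len(nrow(norm))) {
      a <- lg[i, ]; b <- lr[i, ]
      if (stats::var(a) == 0 && stats::var(b) == 0) next  # zero variance: p missing
      p[i] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    }
  }
  out <- data.frame(
    gene = rownames(norm),
    day = day, reference_day = reference_day,
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    p_value = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    significant = !is.na(p) & p < config$p_threshold &
      abs(log2fc) > config$fc_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "method") <- paste0("welch_t_log2(count+", c0, "); normalize=",
                                config$normalize)
  out
}

#' Restrict a differential table to a gene subset and label it
#'
#' Implements the study's volcano views: all genes, the high-confidence
#' surface subset (SPC >= 3), or a glyco-enzyme (CAZy-annotated) list.
#' Rows are sorted by p-value; significant rows carry their gene symbol in
#' the `label` column.
#'
#' @param diffs Output of [differential()].
#' @param subset One of `"all"`, `"spc_high"`, `"cazy"`.
#' @param spc_table Named SPC score vector (required for `"spc_high"`).
#' @param cazy_genes Character vector of glyco-enzyme gene symbols
#'   (required for `"cazy"`).
#' @param spc_threshold SPC floor for the surface subset (default 3).
#' @return The filtered, sorted table with an added `label` column.
#' @export
volcano_table <- function(diffs, subset = c("all", "spc_high", "cazy"),
                          spc_table = NULL, cazy_genes = NULL,
                          spc_threshold = 3) {
  subset <- match.arg(subset)
  out <- diffs
  if (subset == "spc_high") {
    if (is.null(spc_table)) stop("subset 'spc_high' requires an SPC table")
    ann <- annotate_spc(out$gene, spc_table)
    out <- out[!is.na(ann$spc_score) & ann$spc_score >= spc_threshold, ,
               drop = FALSE]
  } else if (subset == "cazy") {
    if (is.null(cazy_genes)) stop("subset 'cazy' requires a gene list")
    out <- out[toupper(out$gene) %in% toupper(cazy_genes), , drop = FALSE]
  }
  out <- out[order(out$p_value), , drop = FALSE]
  out$label <- ifelse(out$significant, out$gene, NA_character_)
  rownames(out) <- NULL
  out
}

#' Build max-normalized transcript and PSM evidence profiles
#'
#' For each protein present in both modalities, averages transcript counts
#' across replicates per day, pairs them with glycopeptide spectral counts
#' (PSMs) per day, and normalizes each modality to its per-protein maximum.
#'
#' @param counts Gene x sample transcript count matrix.
#' @param meta Sample metadata (`sample`, `day`, `replicate`).
#' @param psm Protein x day matrix of PSM counts (column names are days).
#' @param gene_of Optional named vector mapping protein id -> gene symbol;
#'   by default protein ids are assumed to equal gene symbols.
#' @return A list of class `"evidence_profiles"`: `profiles` (long
#'   `data.frame`: `protein`, `day`, `transcript`, `psm`, both in [0,1])
#'   and `detection` (`protein`, `transcript_detected`, `psm_detected`,
#'   `transcript_max`, `psm_max` on the raw scale).
#' @export
evidence_profiles <- function(counts, meta, psm, gene_of = NULL) {
  byday <- average_replicates(counts, meta)
  psm <- as.matrix(psm)
  days <- intersect(colnames(byday), colnames(psm))
  if (length(days) == 0) stop("no shared days between transcript and PSM data")
  proteins <- rownames(psm)
  genes <- if (is.null(gene_of)) proteins else unname(gene_of[proteins])
  keep <- genes %in% rownames(byday)
  proteins <- proteins[keep]; genes <- genes[keep]
  prof <- list(); det <- list()
  for (k in seq_along(proteins)) {
    tr <- byday[genes[k], days]
    ps <- psm[proteins[k], days]
    nt <- normalize_to_max(tr)
    np <- normalize_to_max(ps)
    prof[[k]] <- data.frame(protein = proteins[k], day = as.integer(days),
                            transcript = unname(nt$profile),
                            psm = unname(np$profile), stringsAsFactors = FALSE)
    det[[k]] <- data.frame(protein = proteins[k],
                           transcript_detected = nt$detected,
                           psm_detected = np$detected,
                           transcript_max = max(tr), psm_max = max(ps),
                           stringsAsFactors = FALSE)
  }
  structure(list(profiles = do.call(rbind, prof),
                 detection = do.call(rbind, det)),
            class = "evidence_profiles")
}

#' Transcript-PSM trend concordance per protein
#'
#' Compares the two evidence modalities per protein: the Spearman
#' correlation of the normalized transcript and PSM profiles over shared
#' timepoints (missing when fewer than 3), its sign, and a discordance
#' flag raised when one modality is never detected while the other's raw
#' maximum exceeds a floor (protein detected with silent transcript, or a
#' robust transcript with no glycopeptide evidence).
#'
#' @param ep An [evidence_profiles()] object.
#' @param floor Raw-scale detection floor for the discordance flag
#'   (default 10).
#' @return A `data.frame`: `protein`, `rho`, `direction`
#'   (`"positive"`/`"negative"`/`"none"`/`NA`), `discordant`.
#' @export
evidence_concordance <- function(ep, floor = 10) {
  stopifnot(inherits(ep, "evidence_profiles"))
  out <- lapply(split(ep$profiles, ep$profiles$protein), function(d) {
    rho <- if (nrow(d) >= 3) {
      suppressWarnings(stats::cor(d$transcript, d$psm, method = "spearman"))
    } else NA_real_
    data.frame(protein = d$protein[1], rho = rho, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  det <- ep$detection[match(out$protein, ep$detection$protein), ]
  out$direction <- ifelse(is.na(out$rho), NA_character_,
                          ifelse(out$rho > 0, "positive",
                                 ifelse(out$rho < 0, "negative", "none")))
  out$discordant <- (!det$transcript_detected & det$psm_max >= floor) |
    (!det$psm_detected & det$transcript_max >= floor)
  rownames(out) <- NULL
  out
}
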