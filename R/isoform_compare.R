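# Canonical <-> isoform position correspondence is computed by global
# (end-to-end) pairwise alignment; see align_pair(). Classification of
# sequon changes then only reads the alignment map at Asn coordinates.

#' Alignment scoring configuration
#'
#' Default scoring for canonical-vs-isoform global alignment: BLOSUM62 with
#' affine gaps (open 11, extend 1), the standard protein-alignment setting.
#'
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   \pkg{Biostrings} (e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list with class `"alignment_scoring"`.
#' @export
alignment_scoring <- function(substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

#' Globally align a canonical protein with one of its isoforms
#'
#' Computes an end-to-end pairwise alignment (Needleman-Wunsch with affine
#' gaps, via \pkg{Biostrings}) and converts it to a position map: for every
#' canonical residue, the aligned isoform coordinate or `NA` when the
#' residue falls in a deletion; and the inverse map for isoform residues.
#' Terminal truncations appear as terminal gaps, so sequons falling there
#' are mapped to `NA` like any other deletion. Traceback in the underlying
#' dynamic program is deterministic, making the map reproducible.
#'
#' @param canonical,isoform Single amino-acid strings (non-empty). `X`
#'   residues are aligned like any other residue.
#' @param scoring An [alignment_scoring()] configuration.
#' @param canonical_id,isoform_id Optional identifiers stored in the map.
#' @return An object of class `"alignment_map"`: a list with
#'   `canonical_id`, `isoform_id`, `score`, `map` (integer vector, one
#'   entry per canonical position; `NA` = deleted) and `rmap` (the inverse,
#'   one entry per isoform position; `NA` = inserted).
#' @examples
#' am <- align_pair("MAAANGSAA", "MANGSAA")
#' map_position(am, 5)  # the Asn at canonical position 5 maps to 3
#' @export
align_pair <- function(canonical, isoform, scoring = alignment_scoring(),
                       canonical_id = "canonical", isoform_id = "isoform") {
  if (length(canonical) != 1 || is.na(canonical) || nchar(canonical) == 0 ||
      length(isoform) != 1 || is.na(isoform) || nchar(isoform) == 0) {
    stop("both sequences must be single non-empty strings")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(canonical), Biostrings::AAString(isoform),
    type = "global",
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  gp <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gs <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  stopifnot(length(gp) == length(gs))
  cpos <- cumsum(gp != "-")
  ipos <- cumsum(gs != "-")
  map <- rep(NA_integer_, nchar(canonical))
  both <- gp != "-" & gs != "-"
  map[cpos[both]] <- ipos[both]
  rmap <- rep(NA_integer_, nchar(isoform))
  rmap[ipos[both]] <- cpos[both]
  structure(list(canonical_id = canonical_id, isoform_id = isoform_id,
                 score = Biostrings::score(aln), map = map, rmap = rmap),
            class = "alignment_map")
}

#' Map a canonical position through an alignment
#'
#' @param map An `"alignment_map"` from [align_pair()] (or any list with a
#'   `map` component).
#' @param canonical_pos 1-based canonical coordinate(s).
#' @return Integer vector of isoform coordinates; `NA` where the canonical
#'   residue is deleted in the isoform.
#' @export
map_position <- function(map, canonical_pos) {
  stopifnot(is.list(map), !is.null(map$map))
  if (any(canonical_pos < 1 | canonical_pos > length(map$map))) {
    stop("canonical position out of range 1..", length(map$map))
  }
  map$map[canonical_pos]
}

#' Classify sequon changes between a canonical protein and one isoform
#'
#' Every canonical sequon is classified by following its Asn through the
#' alignment map: if the aligned isoform position also carries a sequon the
#' site is `retained` (same absolute coordinate) or `shifted` (different
#' coordinate); otherwise — Asn deleted, or the aligned Asn no longer
#' completes a sequon — the site is `lost`. Isoform sequons whose Asn is an
#' insertion or aligns to a canonical position without a sequon are
#' `gained`. Retained/shifted status is decided on the Asn coordinate only;
#' the x and +2 residues may differ as long as a valid sequon exists at the
#' aligned Asn.
#'
#' @param canonical_sites,isoform_sites Site tables from [find_sequons()]
#'   run on the two sequences with identical motif classes.
#' @param map The [align_pair()] map for the pair.
#' @return A `data.frame` with one row per sequon of either sequence:
#'   `canonical_id`, `isoform_id`, `status`
#'   (retained/shifted/lost/gained), `canonical_pos`, `isoform_pos`,
#'   `canonical_triplet`, `isoform_triplet`. Each sequon of both sequences
#'   appears in exactly one row.
#' @export
classify_pair <- function(canonical_sites, isoform_sites, map) {
  stopifnot(inherits(map, "alignment_map") || (is.list(map) && !is.null(map$map)))
  cpos <- canonical_sites$position
  ctrip <- canonical_sites$triplet
  qpos <- isoform_sites$position
  qtrip <- isoform_sites$triplet
  if (length(cpos) > 0 && max(cpos) > length(map$map)) {
    stop("canonical site beyond the aligned canonical sequence")
  }
  if (length(qpos) > 0 && max(qpos) > length(map$rmap)) {
    stop("isoform site beyond the aligned isoform sequence")
  }
  rows <- list()
  mapped <- map$map[cpos]                       # NA = Asn deleted
  iso_has <- mapped %in% qpos
  status <- ifelse(!is.na(mapped) & iso_has,
                   ifelse(mapped == cpos, "retained", "shifted"), "lost")
  if (length(cpos) > 0) {
    rows$canonical <- data.frame(
      status = status,
      canonical_pos = cpos,
      isoform_pos = ifelse(status == "lost", NA_integer_, mapped),
      canonical_triplet = ctrip,
      isoform_triplet = ifelse(status == "lost", NA_character_,
                               qtrip[match(mapped, qpos)]),
      stringsAsFactors = FALSE
    )
  }
  # gained: isoform sequons not consumed above
  back <- map$rmap[qpos]
  gained <- is.na(back) | !(back %in% cpos)
  if (any(gained)) {
    rows$gained <- data.frame(
      status = "gained",
      canonical_pos = NA_integer_,
      isoform_pos = qpos[gained],
      canonical_triplet = NA_character_,
      isoform_triplet = qtrip[gained],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0) {
    data.frame(status = character(0), canonical_pos = integer(0),
               isoform_pos = integer(0), canonical_triplet = character(0),
               isoform_triplet = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, unname(rows))
  }
  cbind(canonical_id = rep(map$canonical_id, nrow(out)),
        isoform_id = rep(map$isoform_id, nrow(out)),
        out, stringsAsFactors = FALSE)
}

#' Scan and classify every canonical-isoform pair in a record table
#'
#' Convenience driver: scans all sequences with [scan_proteome()]'s rules,
#' aligns each isoform to its canonical parent, and classifies all sequons.
#' Pairs are processed independently; proteins with several isoforms
#' contribute one classification per pair.
#'
#' @param records A protein record table containing canonical and isoform
#'   rows ([protein_records()]).
#' @inheritParams find_sequons
#' @param scoring An [alignment_scoring()] configuration.
#' @return A change table: the row-bound output of [classify_pair()] over
#'   all pairs.
#' @export
compare_isoforms <- function(records, classes = c("NxS", "NxT"),
                             scoring = alignment_scoring()) {
  validate_protein_records(records)
  iso <- records[records$role == "isoform", , drop = FALSE]
  if (nrow(iso) == 0) {
    return(classify_pair(empty_sequon_table(), empty_sequon_table(),
                         structure(list(canonical_id = character(0),
                                        isoform_id = character(0),
                                        map = integer(0), rmap = integer(0)),
                                   class = "alignment_map"))[0, ])
  }
  seqs <- setNames(records$sequence, records$id)
  out <- lapply(seq_len(nrow(iso)), function(i) {
    cid <- iso$parent_id[i]
    am <- align_pair(seqs[[cid]], iso$sequence[i],
                     scoring = scoring,
                     canonical_id = cid, isoform_id = iso$id[i])
    classify_pair(find_sequons(seqs[[cid]], classes = classes),
                  find_sequons(iso$sequence[i], classes = classes),
                  am)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize sequon changes across canonical-isoform pairs
#'
#' Aggregates a change table into per-pair counts and the study-level
#' tallies: total differing sites (shifted + lost + gained, counted per
#' canonical-isoform pair), fractions of each change type among differing
#' sites, and protein-level counts deduplicated by canonical id (a protein
#' with several isoforms losing the same site counts once).
#'
#' @param changes A change table from [compare_isoforms()] /
#'   [classify_pair()].
#' @return A list of class `"change_summary"`: `per_pair` (data.frame of
#'   counts per pair), `n_retained`, `n_shifted`, `n_lost`, `n_gained`
#'   (site-by-pair tallies), `total_differing_sites`,
#'   `n_unique_differing_sites` (deduplicated by canonical protein and
#'   site coordinate), `n_proteins_with_any_difference`,
#'   `n_proteins_with_lost`, `n_proteins_with_gained`, `fraction_shifted`,
#'   `fraction_lost`, `fraction_gained`.
#' @export
summarize_changes <- function(changes) {
  stopifnot(is.data.frame(changes))
  if (nrow(changes) == 0) {
    per_pair <- data.frame(canonical_id = character(0), isoform_id = character(0),
                           n_retained = integer(0), n_shifted = integer(0),
                           n_lost = integer(0), n_gained = integer(0))
  } else {
    key <- interaction(changes$canonical_id, changes$isoform_id, drop = TRUE)
    tab <- table(key, factor(changes$status,
                             levels = c("retained", "shifted", "lost", "gained")))
    ids <- unique(changes[c("canonical_id", "isoform_id")])
    k <- interaction(ids$canonical_id, ids$isoform_id, drop = TRUE)
    m <- as.matrix(tab)[match(as.character(k), rownames(tab)), , drop = FALSE]
    per_pair <- data.frame(ids, n_retained = m[, "retained"],
                           n_shifted = m[, "shifted"], n_lost = m[, "lost"],
                           n_gained = m[, "gained"], row.names = NULL)
  }
  n_ret <- sum(per_pair$n_retained)
  n_shi <- sum(per_pair$n_shifted)
  n_los <- sum(per_pair$n_lost)
  n_gai <- sum(per_pair$n_gained)
  diff_total <- n_shi + n_los + n_gai
  is_diff <- changes$status != "retained"
  d <- changes[is_diff, , drop = FALSE]
  site_key <- paste(d$canonical_id, d$status,
                    ifelse(is.na(d$canonical_pos), paste0("i", d$isoform_pos),
                           d$canonical_pos))
  structure(list(
    per_pair = per_pair,
    n_retained = n_ret, n_shifted = n_shi, n_lost = n_los, n_gained = n_gai,
    total_differing_sites = diff_total,
    n_unique_differing_sites = length(unique(site_key)),
    n_proteins_with_any_difference = length(unique(d$canonical_id)),
    n_proteins_with_lost = length(unique(d$canonical_id[d$status == "lost"])),
    n_proteins_with_gained = length(unique(d$canonical_id[d$status == "gained"])),
    fraction_shifted = if (diff_total > 0) n_shi / diff_total else NA_real_,
    fraction_lost = if (diff_total > 0) n_los / diff_total else NA_real_,
    fraction_gained = if (diff_total > 0) n_gai / diff_total else NA_real_
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat("Sequon change summary over", nrow(x$per_pair), "canonical-isoform pairs\n")
  cat(sprintf("  retained: %d\n", x$n_retained))
  cat(sprintf("  differing sites (shifted+lost+gained): %d (unique by protein/site: %d)\n",
              x$total_differing_sites, x$n_unique_differing_sites))
  cat(sprintf("  shifted: %d (%.1f%%)  lost: %d (%.1f%%)  gained: %d (%.1f%%)\n",
              x$n_shifted, 100 * x$fraction_shifted,
              x$n_lost, 100 * x$fraction_lost,
              x$n_gained, 100 * x$fraction_gained))
  cat(sprintf("  proteins with any difference: %d (with lost: %d, with gained: %d)\n",
              x$n_proteins_with_any_difference, x$n_proteins_with_lost,
              x$n_proteins_with_gained))
  invisible(x)
}
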