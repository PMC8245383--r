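# FASTA conventions: the description line is "<id> key=value ..." with
# recognized keys role=, parent=, gene=, note=. All coordinates in all
# output tables are 1-based inclusive.

#' Read protein records from FASTA
#'
#' Parses record metadata from header key=value fields (`role=`,
#' `parent=`, `gene=`, `note=`), upper-cases sequences, and strips `*`
#' stop characters with a warning. The resulting table is validated
#' (isoforms must name an existing canonical parent).
#'
#' @param path FASTA file path.
#' @return A [protein_records()] table.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    warning("empty FASTA: ", path)
    return(protein_records(character(0), character(0))[0, ])
  }
  headers <- names(aa)
  seqs <- as.character(aa)
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  field <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  rec <- protein_records(
    id = ids,
    sequence = seqs,
    gene = vapply(headers, field, character(1), key = "gene"),
    role = ifelse(is.na(vapply(headers, field, character(1), key = "role")),
                  "canonical",
                  vapply(headers, field, character(1), key = "role")),
    parent_id = vapply(headers, field, character(1), key = "parent"),
    event_note = vapply(headers, field, character(1), key = "note")
  )
  rec
}

#' Write protein records to FASTA
#'
#' Inverse of [read_protein_fasta()]: metadata is emitted as key=value
#' header fields so a write/read round trip preserves records exactly.
#'
#' @param records A [protein_records()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  validate_protein_records(records)
  hdr <- vapply(seq_len(nrow(records)), function(i) {
    parts <- records$id[i]
    if (!is.na(records$gene[i])) parts <- c(parts, paste0("gene=", records$gene[i]))
    parts <- c(parts, paste0("role=", records$role[i]))
    if (!is.na(records$parent_id[i])) {
      parts <- c(parts, paste0("parent=", records$parent_id[i]))
    }
    if (!is.na(records$event_note[i])) {
      parts <- c(parts, paste0("note=", records$event_note[i]))
    }
    paste(parts, collapse = " ")
  }, character(1))
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    body <- gsub("(.{60})", "\\1\n", records$sequence[i])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", hdr[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a canonical/isoform pair table
#'
#' Reads a delimited (TSV/CSV) export of an isoform prediction table — one
#' row per canonical-isoform pair — into a [protein_records()] table. The
#' file's column names are supplied through `column_map` since deposited
#' tables vary in schema. Rows with an empty or missing sequence are
#' skipped and counted in the `"skipped"` attribute.
#'
#' @param path Delimited text file; `sep` defaults to tab, use `","` for
#'   CSV.
#' @param column_map Named list with entries `canonical_id`,
#'   `canonical_seq`, `isoform_id`, `isoform_seq`, and optionally `gene`,
#'   naming columns of the file.
#' @param sep Field separator.
#' @return A [protein_records()] table with canonical rows first
#'   (deduplicated) followed by isoform rows.
#' @export
read_isoform_table <- function(path,
                               column_map = list(canonical_id = "canonical_id",
                                                 canonical_seq = "canonical_seq",
                                                 isoform_id = "isoform_id",
                                                 isoform_seq = "isoform_seq"),
                               sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- unlist(column_map[c("canonical_id", "canonical_seq",
                              "isoform_id", "isoform_seq")])
  absent <- setdiff(need, names(d))
  if (length(absent) > 0) {
    stop("mapped column(s) not in file: ", paste(absent, collapse = ", "),
         "; available: ", paste(names(d), collapse = ", "))
  }
  gene <- if (!is.null(column_map$gene) && column_map$gene %in% names(d)) {
    d[[column_map$gene]]
  } else NA_character_
  ok <- !is.na(d[[column_map$canonical_seq]]) &
    nzchar(d[[column_map$canonical_seq]]) &
    !is.na(d[[column_map$isoform_seq]]) & nzchar(d[[column_map$isoform_seq]])
  skipped <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  gene <- if (length(gene) > 1) gene[ok] else rep(gene, nrow(d))
  can <- data.frame(id = d[[column_map$canonical_id]],
                    sequence = d[[column_map$canonical_seq]],
                    gene = gene, stringsAsFactors = FALSE)
  can <- can[!duplicated(can$id), , drop = FALSE]
  rec <- rbind(
    data.frame(id = can$id, gene = can$gene,
               sequence = toupper(can$sequence), role = "canonical",
               parent_id = NA_character_, event_note = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = d[[column_map$isoform_id]], gene = gene,
               sequence = toupper(d[[column_map$isoform_seq]]),
               role = "isoform", parent_id = d[[column_map$canonical_id]],
               event_note = NA_character_, stringsAsFactors = FALSE)
  )
  rownames(rec) <- NULL
  validate_protein_records(rec)
  attr(rec, "skipped") <- skipped
  rec
}

#' Read a glyco-enzyme gene list
#'
#' @param path Text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# Stable config fingerprint without external hashing dependencies.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
            .Machine$integer.max)
}

#' Run the sequon comparison pipeline
#'
#' End-to-end driver: scans canonical and isoform sequences for sequons,
#' aligns and classifies every pair, summarizes the changes, and (when an
#' SPC table is supplied) counts lost-or-gained proteins in the
#' high-confidence surface subset. Writes the site table, the change
#' table, and a JSON summary embedding the seed and a config fingerprint,
#' so reruns with the same inputs are byte-identical.
#'
#' @param records A [protein_records()] table (canonical + isoform rows),
#'   or a FASTA path.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param classes Motif classes to scan.
#' @param scoring [alignment_scoring()] for pair alignment.
#' @param spc_table Optional named SPC score vector; enables the surface
#'   summary.
#' @param spc_threshold High-confidence SPC floor (default 3).
#' @param seed Seed recorded in the summary (the pipeline itself is
#'   deterministic).
#' @return A list of class `"pipeline_result"`: `sites`, `changes`,
#'   `summary` ([summarize_changes()]), `n_surface_lost_or_gained`
#'   (`NA` without an SPC table), `seed`, `config_hash`, and the output
#'   `paths`.
#' @export
run_pipeline <- function(records, out_dir = NULL,
                         classes = c("NxS", "NxT"),
                         scoring = alignment_scoring(),
                         spc_table = NULL, spc_threshold = 3,
                         seed = 1L) {
  if (is.character(records) && length(records) == 1) {
    records <- read_protein_fasta(records)
  }
  validate_protein_records(records)
  sites <- scan_proteome(records, classes = classes)
  changes <- compare_isoforms(records, classes = classes, scoring = scoring)
  summ <- summarize_changes(changes)
  n_surface <- NA_integer_
  if (!is.null(spc_table)) {
    d <- changes[changes$status %in% c("lost", "gained"), , drop = FALSE]
    genes <- records$gene[match(d$canonical_id, records$id)]
    ann <- annotate_spc(unique(genes[!is.na(genes)]), spc_table)
    n_surface <- nrow(high_confidence_filter(ann, threshold = spc_threshold))
  }
  cfg <- list(classes = classes, scoring = unclass(scoring),
              spc_threshold = spc_threshold, seed = seed)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(sites = file.path(out_dir, "sequon_sites.tsv"),
                  changes = file.path(out_dir, "sequon_changes.tsv"),
                  summary = file.path(out_dir, "summary.json"))
    write_sequon_table(sites, paths$sites)
    utils::write.table(changes, paths$changes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash(cfg),
           thresholds = list(spc_high = spc_threshold),
           counts = summ[c("n_retained", "n_shifted", "n_lost", "n_gained",
                           "total_differing_sites",
                           "n_unique_differing_sites",
                           "n_proteins_with_any_difference",
                           "n_proteins_with_lost", "n_proteins_with_gained")],
           fractions = summ[c("fraction_shifted", "fraction_lost",
                              "fraction_gained")],
           n_surface_lost_or_gained = n_surface),
      paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  structure(list(sites = sites, changes = changes, summary = summ,
                 n_surface_lost_or_gained = n_surface, seed = seed,
                 config_hash = config_hash(cfg), paths = paths),
            class = "pipeline_result")
}
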