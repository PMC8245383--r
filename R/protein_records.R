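#' Construct a table of protein records
#'
#' A protein record table is the package's central sequence container: one
#' row per amino-acid sequence, either a canonical protein or a predicted
#' splice isoform linked to its canonical parent.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences (the 20 standard
#'   one-letter codes; `X` is tolerated as an unknown residue). Sequences are
#'   upper-cased.
#' @param gene Optional gene symbols (recycled `NA` if absent).
#' @param role Either `"canonical"` or `"isoform"`, per record.
#' @param parent_id For isoform records, the `id` of the canonical record the
#'   isoform derives from. Must be `NA` for canonical records.
#' @param event_note Optional free-text descriptor of the splice event that
#'   produced an isoform.
#'
#' @return A `data.frame` with columns `id`, `gene`, `sequence`, `role`,
#'   `parent_id`, `event_note`, validated by [validate_protein_records()].
#' @examples
#' protein_records(
#'   id = c("P1", "P1-iso1"),
#'   sequence = c("MAAANGSAA", "MANGSAA"),
#'   role = c("canonical", "isoform"),
#'   parent_id = c(NA, "P1")
#' )
#' @export
protein_records <- function(id, sequence, gene = NA_character_,
                            role = "canonical", parent_id = NA_character_,
                            event_note = NA_character_) {
  n <- length(id)
  rec <- data.frame(
    id = as.character(id),
    gene = rep_len(as.character(gene), n),
    sequence = toupper(as.character(sequence)),
    role = rep_len(as.character(role), n),
    parent_id = rep_len(as.character(parent_id), n),
    event_note = rep_len(as.character(event_note), n),
    stringsAsFactors = FALSE
  )
  validate_protein_records(rec)
  rec
}

#' Validate a protein record table
#'
#' Checks the structural invariants of a record table: unique ids, non-empty
#' sequences over the allowed alphabet, valid roles, and referential
#' integrity of isoform `parent_id` links.
#'
#' @param records A `data.frame` as returned by [protein_records()].
#' @return `records`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_protein_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("id", "sequence", "role")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("protein record table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop("duplicate protein ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(is.na(records$sequence)) || any(nchar(records$sequence) < 1)) {
    stop("every record must have a non-empty sequence")
  }
  bad <- grepl(paste0("[^", AA_ALPHABET_CHARS, "]"), records$sequence)
  if (any(bad)) {
    stop("sequence of record '", records$id[which(bad)[1]],
         "' contains characters outside the amino-acid alphabet (20 standard letters plus X)")
  }
  if (!all(records$role %in% c("canonical", "isoform"))) {
    stop("role must be 'canonical' or 'isoform'")
  }
  iso <- records$role == "isoform"
  if (any(iso)) {
    if (!"parent_id" %in% names(records) || any(is.na(records$parent_id[iso]))) {
      stop("isoform records require a parent_id")
    }
    known <- records$id[records$role == "canonical"]
    orphan <- !(records$parent_id[iso] %in% known)
    if (any(orphan)) {
      stop("isoform '", records$id[iso][which(orphan)[1]],
           "' references unknown canonical parent '",
           records$parent_id[iso][which(orphan)[1]], "'")
    }
  }
  invisible(records)
}

# 20 standard residues plus X (unknown); X never completes a sequon.
AA_ALPHABET_CHARS <- "ACDEFGHIKLMNPQRSTVWYX"

# Save/restore the global RNG state around seeded package computations so
# callers' random streams are unaffected.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
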