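# The canonical N-glycosylation sequon is the tripeptide N-x-S/T where x is
# any residue except proline; NxC and a proposed NxV variant can be scanned
# as optional classes. Only the x != P constraint is enforced; the residue
# following the sequon is unconstrained. An unknown residue (X) at the x or
# third position never yields a site.

# Third-position residue defining each motif class.
MOTIF_THIRD <- c(NxS = "S", NxT = "T", NxC = "C", NxV = "V")

#' Motif classes recognized by the sequon scanner
#'
#' @return Character vector `c("NxS", "NxT", "NxC", "NxV")`. The first two
#'   are the canonical sequon classes and the scanner's default; NxC and NxV
#'   are non-canonical classes used mainly for enrichment contrasts.
#' @export
motif_classes <- function() names(MOTIF_THIRD)

check_motif_classes <- function(classes) {
  if (length(classes) == 0) stop("at least one motif class is required")
  unknown <- setdiff(classes, names(MOTIF_THIRD))
  if (length(unknown) > 0) {
    stop("unknown motif class(es): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(names(MOTIF_THIRD), collapse = ", "), ")")
  }
  unique(classes)
}

#' Find N-glycosylation sequons in one protein sequence
#'
#' Scans an amino-acid sequence for tripeptides N-x-Z with x != P and x != X,
#' where Z is the third-position residue of each requested motif class
#' (S, T, C or V). Overlapping sequons (e.g. `"NNSS"`) are each reported.
#'
#' @param sequence A single amino-acid string (upper case; `X` tolerated).
#' @param classes Motif classes to scan for; subset of [motif_classes()].
#'   Defaults to the canonical `NxS`/`NxT` pair.
#' @param flank Number of residues reported on either side of the Asn in the
#'   `flank` column (clipped at the termini).
#'
#' @return A `data.frame` with one row per site, sorted by position:
#'   `position` (1-based index of the Asn), `motif_class`, `triplet`
#'   (the three sequon residues) and `flank`.
#' @examples
#' find_sequons("MNGSA")                 # one NxS site at position 2
#' find_sequons("MNPSA")                 # none: x == P is excluded
#' find_sequons("MNACA", classes = "NxC")
#' @export
find_sequons <- function(sequence, classes = c("NxS", "NxT"), flank = 5L) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    stop("'sequence' must be a single non-empty string")
  }
  classes <- check_motif_classes(classes)
  third <- unname(MOTIF_THIRD[classes])
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) {
    return(empty_sequon_table())
  }
  c1 <- chars[seq_len(n - 2L)]
  c2 <- chars[seq_len(n - 2L) + 1L]
  c3 <- chars[seq_len(n - 2L) + 2L]
  hit <- c1 == "N" & c2 != "P" & c2 != "X" & c3 %in% third
  pos <- which(hit)
  if (length(pos) == 0) {
    return(empty_sequon_table())
  }
  triplet <- paste0(c1[pos], c2[pos], c3[pos])
  cls <- names(MOTIF_THIRD)[match(c3[pos], MOTIF_THIRD)]
  fl <- substring(sequence, pmax(1L, pos - flank), pmin(n, pos + flank))
  data.frame(position = pos, motif_class = cls, triplet = triplet,
             flank = fl, stringsAsFactors = FALSE)
}

empty_sequon_table <- function(with_protein = FALSE) {
  out <- data.frame(position = integer(0), motif_class = character(0),
                    triplet = character(0), flank = character(0),
                    stringsAsFactors = FALSE)
  if (with_protein) out <- cbind(protein_id = character(0), out)
  out
}

#' Scan a set of protein records for sequons
#'
#' Applies [find_sequons()] to every record and returns the concatenated
#' site table keyed by protein id, in stable (`protein_id`, `position`)
#' order.
#'
#' @param records A protein record table ([protein_records()]).
#' @inheritParams find_sequons
#' @return A `data.frame` with columns `protein_id`, `position`,
#'   `motif_class`, `triplet`, `flank`.
#' @export
scan_proteome <- function(records, classes = c("NxS", "NxT"), flank = 5L) {
  validate_protein_records(records)
  classes <- check_motif_classes(classes)
  if (nrow(records) == 0) {
    return(empty_sequon_table(with_protein = TRUE))
  }
  per <- lapply(seq_len(nrow(records)), function(i) {
    s <- find_sequons(records$sequence[i], classes = classes, flank = flank)
    if (nrow(s) == 0) return(NULL)
    cbind(protein_id = records$id[i], s, stringsAsFactors = FALSE)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0) {
    return(empty_sequon_table(with_protein = TRUE))
  }
  out <- do.call(rbind, per)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a sequon site table to TSV
#'
#' @param sites Output of [scan_proteome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequon_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
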