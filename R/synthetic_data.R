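# Synthetic inputs with known ground truth: canonical proteomes, splice
# isoforms derived by a single coordinate-tracked event (so sequon change
# labels come from exact coordinate arithmetic, independent of any
# alignment), negative-binomial count matrices with planted fold changes,
# sparse PSM tables with day-dependent detection, and SPC score draws.
# Every generator is a pure function of (config, seed).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults describe a small but realistic cardiomyocyte-differentiation
#' style study: 200 proteins with lengths ~ N(400, 100) (minimum 50,
#' roughly the scale of human membrane proteins), uniform residue
#' composition, one splice event per isoform drawn evenly from four event
#' types, RNA-seq over days 15/30/45/60 with 3 replicates per day,
#' negative-binomial counts (log-normal baseline means, dispersion 0.1),
#' 10% of genes planted with a 16-fold change (|log2FC| = 4, the study's
#' volcano threshold magnitude), and PSM detection that can switch on at a
#' protein-specific onset day.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from it.
#' @param n_proteins Number of canonical proteins.
#' @param length_mean,length_sd,min_length Sequence length distribution.
#' @param composition Named residue frequency vector (default uniform over
#'   the 20 standard residues).
#' @param sequon_rate Per-position probability of planting a sequon
#'   (non-overlapping N-x-Z triplets) on top of the background
#'   composition; 0 disables planting.
#' @param sequon_classes Third-position residues used when planting
#'   (default S/T).
#' @param event_mix Named probabilities over
#'   `internal_deletion`, `internal_insertion`, `terminal_truncation`,
#'   `segment_substitution`; must sum to 1.
#' @param event_size_mean Mean event size in residues (sizes are
#'   3 + Poisson(mean - 3)).
#' @param days,replicates RNA-seq design.
#' @param nb_mu_meanlog,nb_mu_sdlog Log-normal baseline expression means.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param planted_fraction,planted_magnitude Fraction of genes with a
#'   planted fold change and its magnitude (applied, up or down, to every
#'   non-reference day).
#' @param psm_lambda Mean PSM count when a protein is detected.
#' @param detection_prob Per-day probability of detection after onset.
#' @param late_onset_fraction Fraction of proteins whose PSM evidence
#'   starts only at a random later day.
#' @param spc_probs Probabilities of SPC scores 0..4.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 200L,
                              length_mean = 400, length_sd = 100,
                              min_length = 50,
                              composition = NULL,
                              sequon_rate = 0,
                              sequon_classes = c("S", "T"),
                              event_mix = c(internal_deletion = 0.25,
                                            internal_insertion = 0.25,
                                            terminal_truncation = 0.25,
                                            segment_substitution = 0.25),
                              event_size_mean = 30,
                              days = c(15L, 30L, 45L, 60L),
                              replicates = 3L,
                              nb_mu_meanlog = log(100), nb_mu_sdlog = 1,
                              dispersion = 0.1,
                              planted_fraction = 0.1,
                              planted_magnitude = 16,
                              psm_lambda = 20,
                              detection_prob = 0.8,
                              late_onset_fraction = 0.25,
                              spc_probs = c(0.55, 0.10, 0.10, 0.15, 0.10)) {
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA20)
  }
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  if (abs(sum(event_mix) - 1) > 1e-6) stop("event_mix must sum to 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(length(spc_probs) == 5, abs(sum(spc_probs) - 1) < 1e-6)
  structure(as.list(environment()), class = "simulation_config")
}

random_sequence <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

plant_sequons <- function(chars, rate, classes) {
  n <- length(chars)
  p <- 1L
  while (p <= n - 2L) {
    if (stats::runif(1) < rate) {
      chars[p] <- "N"
      x <- sample(setdiff(AA20, "P"), 1)
      chars[p + 1L] <- x
      chars[p + 2L] <- sample(classes, 1)
      p <- p + 3L
    } else {
      p <- p + 1L
    }
  }
  chars
}

#' Simulate a canonical proteome
#'
#' Draws `n_proteins` sequences from the configured composition,
#' optionally planting non-overlapping sequons at `sequon_rate`.
#' Deterministic for a fixed config (byte-identical FASTA on rerun).
#'
#' @param config A [simulation_config()].
#' @return A canonical [protein_records()] table with ids `P0001...` and
#'   gene symbols `G0001...`.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proteins
  if (n == 0) return(protein_records(character(0), character(0))[0, ])
  with_local_seed(config$seed, {
    lens <- pmax(config$min_length,
                 round(stats::rnorm(n, config$length_mean, config$length_sd)))
    seqs <- vapply(lens, function(L) {
      ch <- sample(names(config$composition), L, replace = TRUE,
                   prob = config$composition)
      if (config$sequon_rate > 0) {
        ch <- plant_sequons(ch, config$sequon_rate, config$sequon_classes)
      }
      paste(ch, collapse = "")
    }, character(1))
    protein_records(id = sprintf("P%04d", seq_len(n)),
                    sequence = seqs,
                    gene = sprintf("G%04d", seq_len(n)))
  })
}

# Exact canonical->isoform coordinate map for one event; NA = deleted.
event_map <- function(L, event) {
  map <- seq_len(L)
  switch(event$type,
    internal_deletion = {
      del <- seq(event$a, event$b)
      map[del] <- NA_integer_
      after <- which(seq_len(L) > event$b)
      map[after] <- map[after] - length(del)
      map
    },
    internal_insertion = {
      after <- which(seq_len(L) > event$a)
      map[after] <- map[after] + event$size
      map
    },
    terminal_truncation = {
      if (event$side == "start") {
        map[seq_len(event$size)] <- NA_integer_
        keep <- which(seq_len(L) > event$size)
        map[keep] <- map[keep] - event$size
      } else {
        map[seq(L - event$size + 1L, L)] <- NA_integer_
      }
      map
    },
    segment_substitution = map
  )
}

apply_event <- function(seq, event, composition) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  switch(event$type,
    internal_deletion = paste(ch[-seq(event$a, event$b)], collapse = ""),
    internal_insertion = paste(c(ch[seq_len(event$a)],
                                 sample(names(composition), event$size,
                                        replace = TRUE, prob = composition),
                                 if (event$a < length(ch))
                                   ch[seq(event$a + 1L, length(ch))]),
                               collapse = ""),
    terminal_truncation = if (event$side == "start") {
      paste(ch[-seq_len(event$size)], collapse = "")
    } else {
      paste(ch[seq_len(length(ch) - event$size)], collapse = "")
    },
    segment_substitution = {
      ch[seq(event$a, event$b)] <- sample(names(composition),
                                          event$b - event$a + 1L,
                                          replace = TRUE, prob = composition)
      paste(ch, collapse = "")
    }
  )
}

# Classify sequon changes from the exact event map (no alignment involved):
# the coordinate-arithmetic oracle for the alignment-based classifier.
classify_from_map <- function(can_sites, iso_sites, map, iso_len) {
  rmap <- rep(NA_integer_, iso_len)
  ok <- !is.na(map)
  rmap[map[ok]] <- which(ok)
  status <- character(nrow(can_sites))
  iso_at <- iso_sites$position
  for (i in seq_len(nrow(can_sites))) {
    q <- map[can_sites$position[i]]
    status[i] <- if (!is.na(q) && q %in% iso_at) {
      if (q == can_sites$position[i]) "retained" else "shifted"
    } else "lost"
  }
  gained <- vapply(iso_at, function(q) {
    b <- rmap[q]
    is.na(b) || !(b %in% can_sites$position)
  }, logical(1))
  data.frame(
    status = c(status, rep("gained", sum(gained))),
    canonical_pos = c(can_sites$position, rep(NA_integer_, sum(gained))),
    isoform_pos = c(ifelse(status == "lost", NA_integer_,
                           map[can_sites$position]),
                    iso_at[gained]),
    stringsAsFactors = FALSE
  )
}

# A pair is "unambiguous" when every sequon is either >= margin residues
# clear of the event footprint or wholly inside the removed/inserted core,
# so its fate follows from coordinate arithmetic alone.
event_unambiguous <- function(event, can_sites, iso_sites, L, iso_len,
                              margin = 3L) {
  core_can <- switch(event$type,
    internal_deletion = c(event$a, event$b),
    segment_substitution = c(event$a, event$b),
    internal_insertion = c(event$a, event$a + 1L),
    terminal_truncation = if (event$side == "start") c(1L, event$size)
                          else c(L - event$size + 1L, L)
  )
  core_iso <- switch(event$type,
    internal_deletion = c(event$a, event$a - 1L),          # junction point
    segment_substitution = c(event$a, event$b),
    internal_insertion = c(event$a + 1L, event$a + event$size),
    terminal_truncation = if (event$side == "start") c(1L, 0L)
                          else c(iso_len + 1L, iso_len)
  )
  clean <- function(p, core, removable) {
    lo <- p; hi <- p + 2L
    if (hi < core[1] - margin || lo > core[2] + margin) return(TRUE)
    removable && lo >= core[1] && hi <= core[2]
  }
  can_removable <- event$type %in% c("internal_deletion", "terminal_truncation",
                                     "segment_substitution")
  iso_insertable <- event$type %in% c("internal_insertion",
                                      "segment_substitution")
  all(vapply(can_sites$position, clean, logical(1),
             core = core_can, removable = can_removable)) &&
    all(vapply(iso_sites$position, clean, logical(1),
               core = core_iso, removable = iso_insertable))
}

#' Simulate splice isoforms with coordinate-derived ground truth
#'
#' Derives one isoform per canonical protein (or per requested event type)
#' by applying a single splice-style event — internal deletion, internal
#' insertion, terminal truncation, or segment substitution — and labels
#' every sequon of the pair as retained/shifted/lost/gained directly from
#' the event's coordinate map. The labels are therefore an alignment-free
#' oracle for [classify_pair()].
#'
#' @param proteome Canonical records from [simulate_proteome()].
#' @param config A [simulation_config()].
#' @param event_type Optional single event type overriding `event_mix`.
#' @param classes Motif classes used when labeling ground truth.
#' @return A list: `records` (isoform [protein_records()] rows), `truth`
#'   (`data.frame` of labeled changes: `canonical_id`, `isoform_id`,
#'   `status`, `canonical_pos`, `isoform_pos`), and `pairs`
#'   (`data.frame`: `canonical_id`, `isoform_id`, `event_type`,
#'   `unambiguous`).
#' @export
simulate_isoforms <- function(proteome, config, event_type = NULL,
                              classes = c("NxS", "NxT")) {
  stopifnot(inherits(config, "simulation_config"), nrow(proteome) > 0)
  with_local_seed(config$seed + 1L, {
    recs <- list(); truths <- list(); pairs <- list()
    for (i in seq_len(nrow(proteome))) {
      seq0 <- proteome$sequence[i]
      L <- nchar(seq0)
      type <- if (is.null(event_type)) {
        sample(names(config$event_mix), 1, prob = config$event_mix)
      } else event_type
      # resample events that do not fit the sequence
      repeat {
        size <- 3L + stats::rpois(1, max(config$event_size_mean - 3, 0))
        if (size <= L - 10L) break
      }
      event <- switch(type,
        internal_deletion = {
          a <- sample(seq(2L, L - size), 1)
          list(type = type, a = a, b = a + size - 1L, size = size)
        },
        internal_insertion = {
          a <- sample(seq(1L, L - 1L), 1)
          list(type = type, a = a, size = size)
        },
        terminal_truncation = list(type = type, size = size,
                                   side = sample(c("start", "end"), 1)),
        segment_substitution = {
          a <- sample(seq(2L, L - size), 1)
          list(type = type, a = a, b = a + size - 1L, size = size)
        },
        stop("unknown event type: ", type)
      )
      iso_seq <- apply_event(seq0, event, config$composition)
      map <- event_map(L, event)
      iso_id <- paste0(proteome$id[i], "-iso1")
      can_sites <- find_sequons(seq0, classes = classes)
      iso_sites <- find_sequons(iso_seq, classes = classes)
      tr <- classify_from_map(can_sites, iso_sites, map, nchar(iso_seq))
      if (nrow(tr) > 0) {
        tr <- cbind(canonical_id = proteome$id[i], isoform_id = iso_id, tr,
                    stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- tr
      }
      pairs[[i]] <- data.frame(
        canonical_id = proteome$id[i], isoform_id = iso_id,
        event_type = type,
        unambiguous = event_unambiguous(event, can_sites, iso_sites,
                                        L, nchar(iso_seq)),
        stringsAsFactors = FALSE
      )
      recs[[i]] <- data.frame(id = iso_id, gene = proteome$gene[i],
                              sequence = iso_seq, role = "isoform",
                              parent_id = proteome$id[i],
                              event_note = type, stringsAsFactors = FALSE)
    }
    truth <- if (length(truths) > 0) do.call(rbind, truths) else
      data.frame(canonical_id = character(0), isoform_id = character(0),
                 status = character(0), canonical_pos = integer(0),
                 isoform_pos = integer(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(records = do.call(rbind, recs), truth = truth,
         pairs = do.call(rbind, pairs))
  })
}

#' Simulate a gene x sample count matrix with planted fold changes
#'
#' Counts are negative binomial with log-normal baseline means; a
#' configured fraction of genes multiplies (or divides) its mean by the
#' planted magnitude on every day after the first (reference) day.
#'
#' @param config A [simulation_config()].
#' @param genes Gene symbols; defaults to `G0001...` of length
#'   `n_proteins`.
#' @return A list: `counts` (matrix), `meta` (`sample`, `day`,
#'   `replicate`), `truth` (`gene`, `base_mean`, `planted`, `direction`,
#'   `factor`).
#' @export
simulate_counts <- function(config, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(config$n_proteins))
  G <- length(genes)
  days <- config$days
  reps <- config$replicates
  with_local_seed(config$seed + 2L, {
    mu0 <- stats::rlnorm(G, config$nb_mu_meanlog, config$nb_mu_sdlog)
    planted <- stats::runif(G) < config$planted_fraction
    direction <- ifelse(stats::runif(G) < 0.5, "up", "down")
    direction[!planted] <- NA_character_
    fac <- ifelse(planted,
                  ifelse(direction == "up", config$planted_magnitude,
                         1 / config$planted_magnitude), 1)
    meta <- data.frame(
      sample = paste0("d", rep(days, each = reps), "_r", rep(seq_len(reps),
                                                             length(days))),
      day = rep(days, each = reps),
      replicate = rep(seq_len(reps), length(days))
    )
    counts <- matrix(0L, nrow = G, ncol = nrow(meta),
                     dimnames = list(genes, meta$sample))
    size <- 1 / config$dispersion
    for (j in seq_len(nrow(meta))) {
      mu <- if (meta$day[j] == days[1]) mu0 else mu0 * fac
      counts[, j] <- stats::rnbinom(G, mu = mu, size = size)
    }
    list(counts = counts, meta = meta,
         truth = data.frame(gene = genes, base_mean = mu0, planted = planted,
                            direction = direction, factor = fac,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a protein x day PSM table
#'
#' Spectral counts are Poisson draws gated by a per-day detection
#' probability; a configurable fraction of proteins has a late onset day
#' before which no PSMs occur (emulating surface proteins that appear only
#' late in differentiation).
#'
#' @param proteins Protein identifiers (row names of the result).
#' @param config A [simulation_config()].
#' @return A list: `psm` (matrix, columns named by day) and `truth`
#'   (`protein`, `onset_day`).
#' @export
simulate_psm <- function(proteins, config) {
  stopifnot(inherits(config, "simulation_config"))
  days <- config$days
  n <- length(proteins)
  with_local_seed(config$seed + 3L, {
    late <- stats::runif(n) < config$late_onset_fraction
    onset <- ifelse(late, days[pmin(length(days),
                                    1L + sample.int(length(days) - 1L, n,
                                                    replace = TRUE))],
                    days[1])
    psm <- matrix(0L, nrow = n, ncol = length(days),
                  dimnames = list(proteins, as.character(days)))
    for (j in seq_along(days)) {
      active <- days[j] >= onset
      det <- active & stats::runif(n) < config$detection_prob
      psm[det, j] <- stats::rpois(sum(det), config$psm_lambda)
    }
    list(psm = psm, truth = data.frame(protein = proteins, onset_day = onset,
                                       stringsAsFactors = FALSE))
  })
}

#' Simulate SPC score assignments
#'
#' @param genes Gene symbols.
#' @param config A [simulation_config()].
#' @return Named integer vector of SPC scores 0..4.
#' @export
simulate_spc <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed + 4L, {
    setNames(sample(0:4, length(genes), replace = TRUE,
                    prob = config$spc_probs), genes)
  })
}
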