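#' Curation configuration
#'
#' Filter thresholds for reference-database construction: sequences shorter
#' than 100 nt, with more than two ambiguous N bases, with unnamed species
#' (labels carrying "sp.", "spp." or "aff."), or belonging to a genus with a
#' single species are excluded. Both boundaries are inclusive on the keep
#' side: exactly 100 nt and exactly 2 Ns are kept.
#'
#' @param min_length minimum sequence length (nt) kept.
#' @param max_n maximum number of N bases kept.
#' @param unnamed_tokens substrings of the species name marking unnamed
#'   species (matched case-insensitively).
#' @param min_species_per_genus minimum species per genus after the
#'   record-level filters; genera below it are excluded (monotypic-genus
#'   rule with the default of 2).
#' @param fungal_max_evalue profile-scan E-value at or below which a record
#'   is flagged as suspected fungal.
#' @param fungal_min_identity minimum similarity to a fungal reference (the
#'   fraction of query positions matched in the best local alignment) that
#'   flags a record.
#' @param drop_fungal whether [build_reference_db()] removes flagged records
#'   (they are always reported in the provenance log).
#' @return an object of class `curation_config`.
#' @export
curation_config <- function(min_length = 100L, max_n = 2L,
                            unnamed_tokens = c("sp.", "spp.", "aff."),
                            min_species_per_genus = 2L,
                            fungal_max_evalue = 0.01,
                            fungal_min_identity = 0.5,
                            drop_fungal = FALSE) {
  if (min_length < 1) stop("min_length must be >= 1")
  if (max_n < 0) stop("max_n must be >= 0")
  structure(list(min_length = as.integer(min_length),
                 max_n = as.integer(max_n),
                 unnamed_tokens = unnamed_tokens,
                 min_species_per_genus = as.integer(min_species_per_genus),
                 fungal_max_evalue = fungal_max_evalue,
                 fungal_min_identity = fungal_min_identity,
                 drop_fungal = isTRUE(drop_fungal)),
            class = "curation_config")
}

count_n <- function(seq) nchar(gsub("[^Nn]", "", seq))

is_unnamed <- function(species, tokens) {
  hit <- rep(FALSE, length(species))
  species <- tolower(species)
  for (tok in tokens) {
    hit <- hit | grepl(tolower(tok), species, fixed = TRUE)
  }
  hit
}

#' Apply the reference-database filters
#'
#' Partitions records into kept and rejected. The rejection reason is the
#' first failing rule in the fixed order length, N count, unnamed-species
#' name, genus occupancy; the genus-occupancy rule (a genus must retain at
#' least `min_species_per_genus` species) is evaluated on the set surviving
#' the first three rules, so the result does not depend on record order.
#'
#' @param records data.frame with `id` and `seq`.
#' @param taxonomy data.frame with `id`, `genus`, `species` (and usually
#'   `group`/`family`) covering every record; a missing row is a hard error.
#' @param config a [curation_config()].
#' @return list with `kept` (records data.frame) and `rejected`
#'   (data.frame `id`, `reason`; reasons are `short`, `ambiguous`, `unnamed`,
#'   `monotypic_genus`). `nrow(kept) + nrow(rejected) == nrow(records)`.
#' @export
apply_filters <- function(records, taxonomy, config = curation_config()) {
  stopifnot(is.data.frame(records))
  tax <- taxonomy[match(records$id, taxonomy$id), ]
  if (nrow(records) && any(is.na(tax$species)))
    stop("records without taxonomy row: ",
         paste(records$id[is.na(tax$species)], collapse = ", "))
  if (!nrow(records)) {
    return(list(kept = records,
                rejected = data.frame(id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[nchar(records$seq) < config$min_length] <- "short"
  ambig <- is.na(reason) & count_n(records$seq) > config$max_n
  reason[ambig] <- "ambiguous"
  unnamed <- is.na(reason) & is_unnamed(tax$species, config$unnamed_tokens)
  reason[unnamed] <- "unnamed"
  surv <- is.na(reason)
  occ <- tapply(tax$species[surv], tax$genus[surv],
                function(s) length(unique(s)))
  low <- names(occ)[occ < config$min_species_per_genus]
  reason[surv & tax$genus %in% low] <- "monotypic_genus"
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       rejected = data.frame(id = records$id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Screen records for suspected fungal contamination
#'
#' Two independent routes, reported separately: a record is flagged
#' `suspect_fungal_hmm` when the fungal anchor profile scores
#' E <= `fungal_max_evalue` on it, and `suspect_fungal_blast` when its best
#' local-alignment similarity against any fungal reference reaches
#' `fungal_min_identity` (similarity = matched query positions / query
#' length). Flags are advisory; dropping is a separate decision.
#'
#' @param records data.frame with `id` and `seq`.
#' @param fungal_profile a [build_profile()] model of a conserved fungal
#'   segment, or `NULL` to skip the profile route.
#' @param fungal_refs character vector of fungal reference sequences; if
#'   empty the similarity route is skipped with a warning.
#' @param config a [curation_config()].
#' @param scoring an [alignment_scoring()] for the similarity route.
#' @param calib_seed calibration seed for profile E-values.
#' @return data.frame `id`, `suspect_fungal_hmm`, `suspect_fungal_blast`.
#' @export
screen_fungal <- function(records, fungal_profile, fungal_refs,
                          config = curation_config(),
                          scoring = alignment_scoring(), calib_seed = 1L) {
  n <- nrow(records)
  hmm <- rep(FALSE, n); blast <- rep(FALSE, n)
  if (n == 0)
    return(data.frame(id = character(0), suspect_fungal_hmm = logical(0),
                      suspect_fungal_blast = logical(0),
                      stringsAsFactors = FALSE))
  if (!is.null(fungal_profile)) {
    for (i in seq_len(n)) {
      hit <- scan_profile(fungal_profile, records$seq[i],
                          calib_seed = calib_seed)
      hmm[i] <- hit$e_value <= config$fungal_max_evalue
    }
  }
  if (length(fungal_refs) == 0) {
    warning("empty fungal reference set: similarity screening skipped")
  } else {
    for (i in seq_len(n)) {
      best <- 0
      for (ref in fungal_refs) {
        st <- .c_sw_stats(records$seq[i], ref, scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend)
        best <- max(best, st$matches / nchar(records$seq[i]))
      }
      blast[i] <- best >= config$fungal_min_identity
    }
  }
  data.frame(id = records$id, suspect_fungal_hmm = hmm,
             suspect_fungal_blast = blast, stringsAsFactors = FALSE)
}

# Center-star multiple alignment: align every sequence to the longest one
# (ties: first) and merge the pairwise alignments on the center coordinates
# ("once a gap, always a gap").
center_star_msa <- function(seqs, scoring = alignment_scoring()) {
  n <- length(seqs)
  if (n == 1) return(matrix(strsplit(seqs, "")[[1]], nrow = 1))
  ci <- which.max(nchar(seqs))
  center <- seqs[ci]
  nc <- nchar(center)
  others <- setdiff(seq_len(n), ci)
  alns <- lapply(others, function(k)
    .c_nw_align(center, seqs[k], scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_extend))
  ins <- integer(nc + 1)  # insertion slots after center position p (0..nc)
  for (a in alns) {
    ca <- strsplit(a$a, "")[[1]]
    insk <- integer(nc + 1)
    p <- 0L
    for (ch in ca) {
      if (ch == "-") insk[p + 1L] <- insk[p + 1L] + 1L else p <- p + 1L
    }
    ins <- pmax(ins, insk)
  }
  width <- nc + sum(ins)
  msa <- matrix("-", nrow = n, ncol = width)
  # lay out the center row
  col_of <- integer(nc)  # master column of center position j
  col <- ins[1]
  for (j in seq_len(nc)) {
    col <- col + 1L
    col_of[j] <- col
    msa[ci, col] <- substr(center, j, j)
    col <- col + ins[j + 1L]
  }
  # expand each pairwise alignment onto the master columns
  for (t in seq_along(others)) {
    ca <- strsplit(alns[[t]]$a, "")[[1]]
    sa <- strsplit(alns[[t]]$b, "")[[1]]
    row <- others[t]
    p <- 0L          # center positions consumed
    used <- 0L       # insertion slots consumed in the current group
    for (q in seq_along(ca)) {
      if (ca[q] == "-") {
        used <- used + 1L
        base_col <- if (p == 0L) 0L else col_of[p]
        msa[row, base_col + used] <- sa[q]
      } else {
        p <- p + 1L
        used <- 0L
        msa[row, col_of[p]] <- sa[q]
      }
    }
  }
  msa
}

msa_consensus <- function(msa) {
  n <- nrow(msa)
  cols <- seq_len(ncol(msa))
  out <- character(0)
  for (j in cols) {
    col <- msa[, j]
    if (sum(col == "-") > n / 2) next  # majority-gap column dropped
    cnt <- vapply(BASES, function(b) sum(col == b), numeric(1))
    if (all(cnt == 0)) { out <- c(out, "N"); next }
    top <- BASES[cnt == max(cnt)]
    out <- c(out, .IUPAC[[paste(sort(top), collapse = "")]])
  }
  paste(out, collapse = "")
}

#' Per-species consensus barcode
#'
#' Builds the representative (reference) sequence of a species from its
#' records: sequences are merged by center-star progressive alignment around
#' the longest record, then per column the majority residue wins, ties
#' become the IUPAC ambiguity code of the tied set, and majority-gap columns
#' are dropped. Deterministic.
#'
#' @param seqs character vector of conspecific sequences (>= 1).
#' @param scoring an [alignment_scoring()].
#' @return the consensus sequence (single string).
#' @export
#' @examples
#' species_consensus(c("ACGT", "ACGT", "ACTT"))
#' species_consensus(c("ACGT", "ACTT"))
species_consensus <- function(seqs, scoring = alignment_scoring()) {
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1) return(seqs)
  msa_consensus(center_star_msa(toupper(seqs), scoring))
}

#' Build the curated reference database
#'
#' Runs the full curation in fixed order: record-level filters
#' ([apply_filters()]), fungal screening ([screen_fungal()], when a fungal
#' profile or reference set is supplied), optional removal of flagged
#' records, and per-species consensus construction. Every decision is
#' recorded in a provenance log.
#'
#' @param records data.frame with `id`, `seq` (typically trimmed ITS2 cores).
#' @param taxonomy covering taxonomy table.
#' @param config a [curation_config()].
#' @param fungal_profile,fungal_refs see [screen_fungal()]; both `NULL`/empty
#'   skips screening.
#' @param scoring an [alignment_scoring()].
#' @return an object of class `reference_db`: `records` (curated records with
#'   lineage columns), `taxonomy`, `consensus` (one row per retained
#'   species), `provenance` (id, decision, reason) and `config`.
#' @export
build_reference_db <- function(records, taxonomy, config = curation_config(),
                               fungal_profile = NULL,
                               fungal_refs = character(0),
                               scoring = alignment_scoring()) {
  flt <- apply_filters(records, taxonomy, config)
  prov <- data.frame(id = flt$rejected$id,
                     decision = rep("rejected", nrow(flt$rejected)),
                     reason = flt$rejected$reason, stringsAsFactors = FALSE)
  kept <- flt$kept
  if (!is.null(fungal_profile) || length(fungal_refs)) {
    flags <- screen_fungal(kept, fungal_profile, fungal_refs, config, scoring)
    suspect <- flags$suspect_fungal_hmm | flags$suspect_fungal_blast
    if (any(suspect)) {
      why <- ifelse(flags$suspect_fungal_hmm & flags$suspect_fungal_blast,
                    "suspect_fungal_hmm+blast",
                    ifelse(flags$suspect_fungal_hmm, "suspect_fungal_hmm",
                           "suspect_fungal_blast"))
      decision <- if (config$drop_fungal) "rejected" else "flagged"
      prov <- rbind(prov, data.frame(id = flags$id[suspect],
                                     decision = decision,
                                     reason = why[suspect],
                                     stringsAsFactors = FALSE))
      if (config$drop_fungal)
        kept <- kept[!kept$id %in% flags$id[suspect], , drop = FALSE]
    }
  }
  if (!nrow(kept)) stop("no records survive curation: empty reference database")
  prov <- rbind(prov, data.frame(id = kept$id,
                                 decision = rep("kept", nrow(kept)),
                                 reason = rep("", nrow(kept)),
                                 stringsAsFactors = FALSE))
  tax <- taxonomy[match(kept$id, taxonomy$id), ]
  kept_full <- data.frame(kept,
                          tax[, c("group", "family", "genus", "species")],
                          row.names = NULL, stringsAsFactors = FALSE)
  cons <- do.call(rbind, lapply(split(kept_full, kept_full$species),
                                function(df) {
    data.frame(species = df$species[1], genus = df$genus[1],
               family = df$family[1], group = df$group[1],
               n_records = nrow(df),
               seq = species_consensus(df$seq, scoring),
               stringsAsFactors = FALSE)
  }))
  rownames(cons) <- NULL
  structure(list(records = kept_full,
                 taxonomy = kept_full[, c("id", "group", "family", "genus",
                                          "species")],
                 consensus = cons, provenance = prov, config = config),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("ITS2 reference database:", nrow(x$records), "records,",
      nrow(x$consensus), "species consensus barcodes\n")
  rej <- x$provenance[x$provenance$decision == "rejected", ]
  if (nrow(rej)) {
    cat("Rejections:\n")
    print(table(rej$reason))
  }
  invisible(x)
}

#' Serialize a reference database to a directory
#'
#' Writes `refdb.fasta` (curated records), `consensus.fasta` (one record per
#' species), `taxonomy.tsv` and `provenance.tsv`.
#'
#' @param db a `reference_db`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(db$records$id, db$records$seq, file.path(dir, "refdb.fasta"))
  write_fasta(gsub(" ", "_", db$consensus$species), db$consensus$seq,
              file.path(dir, "consensus.fasta"))
  write_tsv(db$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(db$consensus[, c("species", "genus", "family", "group",
                             "n_records")],
            file.path(dir, "consensus_index.tsv"))
  write_tsv(db$provenance, file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' Load a reference database written by [write_reference_db()]
#'
#' @param dir the database directory.
#' @return a `reference_db` object.
#' @export
read_reference_db <- function(dir) {
  recs <- read_fasta(file.path(dir, "refdb.fasta"))[, c("id", "seq")]
  tax <- read_tsv(file.path(dir, "taxonomy.tsv"))
  cons_seq <- read_fasta(file.path(dir, "consensus.fasta"))
  cons_idx <- read_tsv(file.path(dir, "consensus_index.tsv"))
  prov <- read_tsv(file.path(dir, "provenance.tsv"))
  prov$reason <- ifelse(is.na(prov$reason), "", as.character(prov$reason))
  cons <- data.frame(cons_idx[, c("species", "genus", "family", "group",
                                  "n_records")],
                     seq = cons_seq$seq[match(gsub(" ", "_", cons_idx$species),
                                              cons_seq$id)],
                     stringsAsFactors = FALSE)
  kept_full <- data.frame(recs, tax[match(recs$id, tax$id),
                                    c("group", "family", "genus", "species")],
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = kept_full,
                 taxonomy = kept_full[, c("id", "group", "family", "genus",
                                          "species")],
                 consensus = cons[, c("species", "genus", "family", "group",
                                      "n_records", "seq")],
                 provenance = prov, config = curation_config()),
            class = "reference_db")
}
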