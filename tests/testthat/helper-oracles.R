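# Independent oracles used across the suite.

# Exhaustive enumeration of all global alignments under affine gap costs
# (first gap character costs `open`, each further one `extend`). Exponential;
# only for short sequences.
brute_force_global_score <- function(a, b, match = 1, mismatch = -1,
                                     open = -5, extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (av[i + 1] == bv[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i < n) { # gap character in b, consumes a
      pen <- if (prev == "x") extend else open
      best <- max(best, pen + rec(i + 1, j, "x"))
    }
    if (j < m) { # gap character in a, consumes b
      pen <- if (prev == "y") extend else open
      best <- max(best, pen + rec(i, j + 1, "y"))
    }
    best
  }
  rec(0L, 0L, "s")
}

# Biostrings-based alignment scores with the package's default scoring
# (match 1 / mismatch -1 / gap open -5 / extend -1); Biostrings charges
# gapOpening + L * gapExtension for a length-L gap, hence 4/1.
bs_score <- function(a, b, type) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b), type = type,
                                substitutionMatrix = mat, gapOpening = 4,
                                gapExtension = 1, scoreOnly = TRUE)
}

bs_local_scores <- function(query, subjects) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(subjects), Biostrings::DNAString(query),
    type = "local", substitutionMatrix = mat, gapOpening = 4,
    gapExtension = 1, scoreOnly = TRUE))
}

# Independent nearest-neighbour identification: exhaustive Biostrings local
# alignment, top tier by exact score equality, trichotomy statuses.
oracle_identify <- function(queries, db_records, taxonomy,
                            leave_one_out = TRUE) {
  out <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    subs <- db_records
    if (leave_one_out) subs <- subs[subs$id != q$id, , drop = FALSE]
    sc <- bs_local_scores(q$seq, subs$seq)
    top_ids <- subs$id[sc == max(sc)]
    tt <- taxonomy[match(top_ids, taxonomy$id), ]
    truth <- taxonomy[match(q$id, taxonomy$id), ]
    sp <- unique(tt$species); gn <- unique(tt$genus)
    data.frame(
      query_id = q$id,
      status_species = if (length(sp) > 1) "ambiguous"
        else if (sp == truth$species) "correct" else "incorrect",
      status_genus = if (length(gn) > 1) "ambiguous"
        else if (gn == truth$genus) "correct" else "incorrect",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Wrap records + taxonomy as a reference_db without running curation.
make_ref_db <- function(records, taxonomy) {
  tax <- taxonomy[match(records$id, taxonomy$id), ]
  full <- data.frame(records,
                     tax[, c("group", "family", "genus", "species")],
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = full,
                 taxonomy = full[, c("id", "group", "family", "genus",
                                     "species")],
                 consensus = NULL, provenance = NULL,
                 config = curation_config()),
            class = "reference_db")
}

# Replay the first uniform draw of a seeded degradation pass and count how
# many records fall below `rate` (the expected tag count).
with_seed_replay <- function(seed, n, rate) {
  u <- its2eval:::with_seed(seed, runif(n))
  sum(u < rate)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Build an aligned (gap-free, equal-length) pair with the requested numbers
# of transitions and transversions among `n` columns.
pair_with_pq <- function(n_ts, n_tv, n) {
  a <- rep("A", n)
  b <- a
  if (n_ts) b[seq_len(n_ts)] <- "G"                 # A->G transition
  if (n_tv) b[n_ts + seq_len(n_tv)] <- "T"          # A->T transversion
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
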