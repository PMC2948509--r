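#' Rank database records by local-alignment similarity to a query
#'
#' Scores every non-excluded database record against the query by affine-gap
#' Smith-Waterman local alignment (same scoring as the distance machinery)
#' and returns the ranked hit list. Ties share the extremal (minimum) rank.
#' Ordering is deterministic: score descending, subject id ascending. An
#' optional shared-k-mer pre-screen skips full alignment for subjects that
#' share no k-mer with the query; such subjects score 0, which cannot
#' displace the top tier as long as any subject shares a k-mer.
#'
#' @param query a nucleotide sequence (single string).
#' @param db a `reference_db`, or a data.frame with `id` and `seq`.
#' @param exclude character vector of record ids excluded from the search.
#' @param scoring an [alignment_scoring()].
#' @param use_kmer_filter enable the shared-k-mer pre-screen.
#' @param k k-mer size of the pre-screen.
#' @return data.frame `subject_id`, `score`, `rank`, sorted by rank.
#' @export
similarity_search <- function(query, db, exclude = character(0),
                              scoring = alignment_scoring(),
                              use_kmer_filter = FALSE, k = 8L) {
  recs <- if (inherits(db, "reference_db")) db$records else db
  recs <- recs[!recs$id %in% exclude, , drop = FALSE]
  if (!nrow(recs)) stop("database empty after exclusion")
  query <- toupper(as.character(query))
  scores <- rep(0, nrow(recs))
  todo <- seq_len(nrow(recs))
  if (use_kmer_filter && nchar(query) >= k) {
    qk <- unique(substring(query, 1:(nchar(query) - k + 1),
                           k:nchar(query)))
    shares <- vapply(recs$seq, function(s) {
      if (nchar(s) < k) return(FALSE)
      any(vapply(qk, function(km) grepl(km, s, fixed = TRUE), logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    todo <- which(shares)
  }
  if (length(todo))
    scores[todo] <- .c_sw_scores(query, recs$seq[todo], scoring$match,
                                 scoring$mismatch, scoring$gap_open,
                                 scoring$gap_extend)
  ord <- order(-scores, recs$id)
  out <- data.frame(subject_id = recs$id[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  # ties share the extremal (minimum) rank
  out$rank <- vapply(out$score, function(s) min(which(out$score == s)),
                     integer(1))
  out
}

#' Top-hit (BLAST1) species assignment for one query
#'
#' Implements the top-hit identification rule: the query is assigned to the
#' species of its highest-scoring database hit. If the top tier (all hits
#' tied at rank 1) spans a single species, the assignment is compared with
#' the truth at species and genus level; if it spans several species the
#' query is ambiguous at the species level, and likewise at the genus level
#' only when the tied set spans several genera (a tie within one genus still
#' resolves the genus).
#'
#' @param query a list/data.frame row with `id` and `seq`.
#' @param db a `reference_db` (its taxonomy supplies subject lineages).
#' @param taxonomy taxonomy table used to look up the query's true lineage;
#'   defaults to the database taxonomy.
#' @param leave_one_out exclude the query's own record id from the database
#'   (the standard evaluation protocol; without it every query trivially
#'   matches itself).
#' @param scoring an [alignment_scoring()].
#' @param use_kmer_filter,k forwarded to [similarity_search()].
#' @return an object of class `identification_result`.
#' @export
blast1_identify <- function(query, db, taxonomy = db$taxonomy,
                            leave_one_out = TRUE,
                            scoring = alignment_scoring(),
                            use_kmer_filter = FALSE, k = 8L) {
  ti <- match(query$id, taxonomy$id)
  if (is.na(ti)) stop("query '", query$id, "' has no taxonomy row")
  true_species <- taxonomy$species[ti]
  true_genus <- taxonomy$genus[ti]
  exclude <- if (leave_one_out) query$id else character(0)
  hits <- similarity_search(query$seq, db, exclude = exclude,
                            scoring = scoring,
                            use_kmer_filter = use_kmer_filter, k = k)
  top <- hits[hits$rank == 1, , drop = FALSE]
  dtax <- db$taxonomy
  top_species <- unique(dtax$species[match(top$subject_id, dtax$id)])
  top_genus <- unique(dtax$genus[match(top$subject_id, dtax$id)])
  assigned <- if (length(top_species) == 1) top_species else NA_character_
  status_species <- if (length(top_species) > 1) "ambiguous"
    else if (assigned == true_species) "correct" else "incorrect"
  assigned_genus <- if (length(top_genus) == 1) top_genus else NA_character_
  status_genus <- if (length(top_genus) > 1) "ambiguous"
    else if (assigned_genus == true_genus) "correct" else "incorrect"
  species_in_db <- true_species %in%
    dtax$species[!dtax$id %in% exclude]
  structure(list(query_id = query$id, true_species = true_species,
                 true_genus = true_genus, top_species = top_species,
                 assigned_species = assigned,
                 assigned_genus = assigned_genus,
                 status_species = status_species,
                 status_genus = status_genus,
                 top_score = if (nrow(top)) top$score[1] else NA_real_,
                 n_tied = nrow(top), species_in_db = species_in_db),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("%s: species %s (%s), genus %s\n", x$query_id,
              ifelse(is.na(x$assigned_species), "-", x$assigned_species),
              x$status_species, x$status_genus))
  invisible(x)
}

#' Identify a batch of queries
#'
#' @param queries data.frame with `id`, `seq`.
#' @inheritParams blast1_identify
#' @return data.frame with one row per query: truth, assignment, statuses at
#'   both levels, top score, tie size and whether the true species was
#'   present in the searched database.
#' @export
identify_batch <- function(queries, db, taxonomy = db$taxonomy,
                           leave_one_out = TRUE,
                           scoring = alignment_scoring(),
                           use_kmer_filter = FALSE, k = 8L) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    r <- blast1_identify(queries[i, ], db, taxonomy, leave_one_out, scoring,
                         use_kmer_filter, k)
    data.frame(query_id = r$query_id, true_species = r$true_species,
               true_genus = r$true_genus,
               assigned_species = r$assigned_species,
               assigned_genus = r$assigned_genus,
               status_species = r$status_species,
               status_genus = r$status_genus, top_score = r$top_score,
               n_tied = r$n_tied, species_in_db = r$species_in_db,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Success-rate evaluation of top-hit identification
#'
#' Scores every query with the top-hit rule (leave-one-out by default) and
#' aggregates correct/ambiguous/incorrect percentages per taxon grouping at
#' the requested rank, the summary behind barcode identification-efficiency
#' tables.
#'
#' @param queries data.frame with `id`, `seq`; every query id must be present
#'   in the taxonomy.
#' @param db a `reference_db`.
#' @param taxonomy taxonomy table for query truth; defaults to the database
#'   taxonomy.
#' @param group_by `"group"` (taxon set), `"family"` or `"genus"`.
#' @param level `"species"` or `"genus"`.
#' @param leave_one_out see [blast1_identify()].
#' @param fold_incorrect_into_ambiguous report only two outcome columns by
#'   counting incorrect assignments as ambiguous (the two-column
#'   presentation of published efficiency tables).
#' @param results precomputed [identify_batch()] output, to evaluate several
#'   groupings/levels without re-searching.
#' @param scoring an [alignment_scoring()].
#' @return a data.frame of class `success_report`: one row per group with
#'   `n_species`, `n_queries` and percentage columns (summing to 100 within
#'   rounding). The per-query results are attached as attribute
#'   `"identifications"`.
#' @export
evaluate_success <- function(queries, db, taxonomy = db$taxonomy,
                             group_by = c("group", "family", "genus"),
                             level = c("species", "genus"),
                             leave_one_out = TRUE,
                             fold_incorrect_into_ambiguous = FALSE,
                             results = NULL,
                             scoring = alignment_scoring()) {
  group_by <- match.arg(group_by)
  level <- match.arg(level)
  miss <- setdiff(queries$id, taxonomy$id)
  if (length(miss))
    stop("queries outside the taxonomy universe: ",
         paste(miss, collapse = ", "))
  if (is.null(results))
    results <- identify_batch(queries, db, taxonomy, leave_one_out, scoring)
  qt <- taxonomy[match(results$query_id, taxonomy$id), ]
  status <- results[[paste0("status_", level)]]
  if (fold_incorrect_into_ambiguous)
    status[status == "incorrect"] <- "ambiguous"
  key <- qt[[group_by]]
  rows <- lapply(split(seq_along(key), key), function(ix) {
    n <- length(ix)
    data.frame(group = key[ix[1]], level = level,
               n_species = length(unique(qt$species[ix])), n_queries = n,
               pct_correct = 100 * sum(status[ix] == "correct") / n,
               pct_ambiguous = 100 * sum(status[ix] == "ambiguous") / n,
               pct_incorrect = 100 * sum(status[ix] == "incorrect") / n,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  rownames(rep_df) <- NULL
  attr(rep_df, "identifications") <- results
  class(rep_df) <- c("success_report", "data.frame")
  rep_df
}
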