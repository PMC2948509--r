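#' Build a position-specific profile from an aligned conserved segment
#'
#' Constructs a position-specific scoring model (match-state emissions with
#' affine gap penalties, scored as log-odds against a background composition)
#' from a gapped alignment of a conserved anchor segment, e.g. the 5.8S tail
#' or 28S head used to delimit ITS2. Columns whose gap fraction exceeds 0.5
#' are dropped from the match states. Emissions are pseudocount-smoothed:
#' `(count + pseudocount * background) / (residues + pseudocount)`.
#'
#' @param alignment a character vector of >= 2 equal-length aligned rows
#'   (alphabet A/C/G/T/N/-; U is normalized to T), or the path to an aligned
#'   FASTA file.
#' @param pseudocount non-negative smoothing weight.
#' @param background length-4 background composition over A,C,G,T.
#' @param gap_open,gap_extend affine gap penalties in bits (negative),
#'   applied per model column to insertions and deletions.
#' @return an object of class `profile_model`.
#' @export
#' @examples
#' m <- build_profile(c("ACGT", "ACGT"), pseudocount = 1)
#' m$length
build_profile <- function(alignment, pseudocount = 1,
                          background = rep(0.25, 4),
                          gap_open = -4, gap_extend = -1) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    alignment <- read_fasta(alignment)$seq
  }
  if (length(alignment) < 2) stop("alignment needs at least 2 rows")
  alignment <- chartr("U", "T", toupper(alignment))
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ","))
  if (any(grepl("[^ACGTN-]", alignment)))
    stop("alignment alphabet must be A/C/G/T/N/-")
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive frequencies")
  background <- background / sum(background)
  if (pseudocount < 0) stop("pseudocount must be >= 0")

  mat <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("all columns are majority-gap; no match states")
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  if (L < 5) stop("model length must be >= 5 (got ", L, ")")

  counts <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    vapply(BASES, function(b) sum(col == b), numeric(1))
  }, numeric(4))                      # 4 x L
  m_col <- colSums(counts)            # residues per column (gaps/N excluded)
  emissions <- (counts + pseudocount * background) /
    rep(m_col + pseudocount, each = 4)
  dimnames(emissions) <- list(BASES, NULL)
  log_odds <- log2(emissions / background)
  consensus <- paste(BASES[apply(emissions, 2, which.max)], collapse = "")
  structure(list(emissions = emissions, log_odds = log_odds,
                 background = background,
                 gap_open = rep(gap_open, L), gap_extend = rep(gap_extend, L),
                 length = L, pseudocount = pseudocount,
                 consensus = consensus),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Profile model:", x$length, "match columns\n")
  cat("Consensus:", x$consensus, "\n")
  invisible(x)
}

# Gumbel parameters fitted by method of moments to null best scores.
gumbel_fit <- function(scores) {
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-12) return(list(lambda = Inf, mu = mean(scores)))
  lambda <- pi / (s * sqrt(6))
  list(lambda = lambda, mu = mean(scores) - .EULER_GAMMA / lambda)
}

#' Scan a profile against a sequence
#'
#' Finds the best glocal (whole model, local target) alignment of the profile
#' against a sequence by Viterbi dynamic programming in log-odds space, then
#' attaches an E-value from a Gumbel null fitted by the method of moments to
#' the best scores of seeded shuffles of the target. The E-value is scaled to
#' the calibration ensemble (`n_shuffle` targets), so an unrelated random
#' sequence typically scores E >> 1 while a genuine anchor occurrence scores
#' E near 0. On equal score the leftmost, lowest-start hit wins.
#'
#' @param model a [build_profile()] model.
#' @param seq a nucleotide sequence (single string) to scan.
#' @param calib_seed integer seed for the shuffle null; fixing it makes
#'   E-values reproducible.
#' @param n_shuffle number of shuffled targets used for calibration.
#' @param target_id optional id reported in the hit.
#' @return an object of class `profile_hit`: `target_id`, `start`, `end`
#'   (0-based half-open interval on the target), `score` (bits), `e_value`,
#'   and the fitted `lambda`/`mu`.
#' @export
scan_profile <- function(model, seq, calib_seed = 1L, n_shuffle = 200L,
                         target_id = NA_character_) {
  stopifnot(inherits(model, "profile_model"))
  seq <- chartr("U", "T", toupper(as.character(seq)))
  if (length(seq) != 1 || is.na(seq) || nchar(seq) < 1)
    stop("sequence must be a single non-empty string")
  hit <- .c_profile_scan(model$log_odds, model$gap_open, model$gap_extend, seq)
  null <- .c_profile_calibrate(model$log_odds, model$gap_open,
                               model$gap_extend, seq,
                               as.integer(n_shuffle), as.integer(calib_seed))
  fit <- gumbel_fit(null)
  e_value <- if (is.infinite(fit$lambda)) {
    if (hit$score > fit$mu) 0 else as.numeric(n_shuffle)
  } else {
    n_shuffle * exp(-fit$lambda * (hit$score - fit$mu))
  }
  structure(list(target_id = target_id, start = hit$start, end = hit$end,
                 score = hit$score, e_value = e_value,
                 lambda = fit$lambda, mu = fit$mu,
                 n_shuffle = as.integer(n_shuffle),
                 calib_seed = as.integer(calib_seed)),
            class = "profile_hit")
}

#' @export
print.profile_hit <- function(x, ...) {
  cat(sprintf("Profile hit %s: [%d, %d) score %.2f bits, E = %.3g\n",
              ifelse(is.na(x$target_id), "", x$target_id),
              x$start, x$end, x$score, x$e_value))
  invisible(x)
}

#' Delimit the ITS2 core of one record
#'
#' Locates the conserved 5.8S-tail and 28S-head anchors with the two profile
#' models and, when both are found at E <= `max_evalue`, non-overlapping and
#' in the expected order, reports the ITS2 core as the interval between the
#' end of the 5.8S hit and the start of the 28S hit (both anchors excluded).
#' Failures are reported as statuses, never as errors.
#'
#' @param record a list/data.frame row with `id` and `seq`, or a plain
#'   sequence string.
#' @param model_5_8S,model_28S [build_profile()] models for the two anchors.
#' @param max_evalue acceptance threshold for anchor hits (default 1.0).
#' @param calib_seed,n_shuffle E-value calibration controls, see
#'   [scan_profile()].
#' @return an object of class `annotation_result` with the two hits, the
#'   `its2_interval` (0-based half-open) and trimmed `its2_seq` when
#'   annotated, and `status` one of `annotated`, `no_5_8S`, `no_28S`,
#'   `inverted`.
#' @export
annotate_its2 <- function(record, model_5_8S, model_28S, max_evalue = 1.0,
                          calib_seed = 1L, n_shuffle = 200L) {
  if (is.character(record)) record <- list(id = NA_character_, seq = record)
  hit58 <- scan_profile(model_5_8S, record$seq, calib_seed, n_shuffle,
                        target_id = record$id)
  hit28 <- scan_profile(model_28S, record$seq, calib_seed, n_shuffle,
                        target_id = record$id)
  ok58 <- hit58$e_value <= max_evalue
  ok28 <- hit28$e_value <= max_evalue
  interval <- NULL; its2_seq <- NA_character_
  if (!ok58) {
    status <- "no_5_8S"
  } else if (!ok28) {
    status <- "no_28S"
  } else if (hit58$end <= hit28$start) {
    status <- "annotated"
    interval <- c(hit58$end, hit28$start)
    its2_seq <- substr(record$seq, hit58$end + 1L, hit28$start)
  } else {
    status <- "inverted"
  }
  structure(list(id = record$id, hit_5_8S = if (ok58) hit58 else NULL,
                 hit_28S = if (ok28) hit28 else NULL,
                 raw_hit_5_8S = hit58, raw_hit_28S = hit28,
                 its2_interval = interval, its2_seq = its2_seq,
                 status = status), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("Annotation %s: %s", ifelse(is.na(x$id), "", x$id), x$status))
  if (!is.null(x$its2_interval))
    cat(sprintf(" core [%d, %d)", x$its2_interval[1], x$its2_interval[2]))
  cat("\n")
  invisible(x)
}

#' Annotate a batch of records
#'
#' Applies [annotate_its2()] to every record independently (order-preserving,
#' no cross-record state) and collects a tabular report plus the trimmed core
#' sequences of the records that annotated.
#'
#' @param records data.frame with columns `id` and `seq`.
#' @inheritParams annotate_its2
#' @return list with `results` (one row per record: statuses, hit intervals,
#'   E-values, core interval) and `trimmed` (named character vector of ITS2
#'   cores for `annotated` records).
#' @export
annotate_batch <- function(records, model_5_8S, model_28S, max_evalue = 1.0,
                           calib_seed = 1L, n_shuffle = 200L) {
  stopifnot(is.data.frame(records))
  res <- lapply(seq_len(nrow(records)), function(i)
    annotate_its2(records[i, ], model_5_8S, model_28S, max_evalue,
                  calib_seed, n_shuffle))
  grab <- function(f) vapply(res, f, numeric(1))
  results <- data.frame(
    id = if (nrow(records)) records$id else character(0),
    status = vapply(res, function(r) r$status, character(1)),
    start_5_8S = grab(function(r) r$raw_hit_5_8S$start),
    end_5_8S = grab(function(r) r$raw_hit_5_8S$end),
    evalue_5_8S = grab(function(r) r$raw_hit_5_8S$e_value),
    start_28S = grab(function(r) r$raw_hit_28S$start),
    end_28S = grab(function(r) r$raw_hit_28S$end),
    evalue_28S = grab(function(r) r$raw_hit_28S$e_value),
    core_start = grab(function(r)
      if (is.null(r$its2_interval)) NA_real_ else r$its2_interval[1]),
    core_end = grab(function(r)
      if (is.null(r$its2_interval)) NA_real_ else r$its2_interval[2]),
    stringsAsFactors = FALSE)
  ann <- results$status == "annotated"
  trimmed <- setNames(vapply(res[ann], function(r) r$its2_seq, character(1)),
                      results$id[ann])
  list(results = results, trimmed = trimmed)
}

#' Write trimmed ITS2 cores from an annotation batch
#'
#' @param batch result of [annotate_batch()].
#' @param path output FASTA path; descriptions carry
#'   `its2=<start>-<end> evalue5.8S=<x> evalue28S=<y>`.
#' @return `path`, invisibly.
#' @export
write_trimmed_fasta <- function(batch, path) {
  r <- batch$results
  ann <- r[r$status == "annotated", , drop = FALSE]
  desc <- sprintf("its2=%d-%d evalue5.8S=%.3g evalue28S=%.3g",
                  as.integer(ann$core_start), as.integer(ann$core_end),
                  ann$evalue_5_8S, ann$evalue_28S)
  write_fasta(ann$id, batch$trimmed[ann$id], path, desc = desc)
}
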