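#' Alignment scoring configuration
#'
#' Conventional DNA scoring shared by the pairwise-distance and
#' identification machinery so that similarity rankings and distance
#' rankings are mutually consistent. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @return an object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = -5,
                              gap_extend = -1) {
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_scoring")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties. Tie-breaking
#' is deterministic: on equal score a substitution is preferred over a gap in
#' `a`, which is preferred over a gap in `b`.
#'
#' @param a,b nucleotide sequences (non-empty strings).
#' @param scoring an [alignment_scoring()] object.
#' @param ids optional length-2 character vector of source ids.
#' @return an object of class `aligned_pair`: gapped sequences `a` and `b` of
#'   equal length and the alignment `score`.
#' @export
#' @examples
#' align_pair("ACGT", "AGT")
align_pair <- function(a, b, scoring = alignment_scoring(), ids = NULL) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .c_nw_align(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                   scoring$gap_extend)
  structure(list(a = r$a, b = r$b, score = r$score, ids = ids),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(x$a, "\n", x$b, "\n", sep = "")
  cat("score:", x$score, "\n")
  invisible(x)
}

#' Kimura two-parameter distance of an aligned pair
#'
#' Over the comparable columns (both residues in A/C/G/T; gap and N columns
#' are excluded), computes the transition proportion P, the transversion
#' proportion Q and the K2P distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#' When a log argument is non-positive the distance is undefined and the pair
#' is flagged invalid (saturation), rather than clamped.
#'
#' @param pair an [align_pair()] result, or a list with gapped `a` and `b`.
#' @return an object of class `k2p_result`: `P`, `Q`, `n_comparable`, `d`,
#'   `valid`.
#' @export
#' @examples
#' k2p_distance(align_pair("ACGTACGT", "ACGTACGT"))
k2p_distance <- function(pair) {
  av <- strsplit(toupper(pair$a), "")[[1]]
  bv <- strsplit(toupper(pair$b), "")[[1]]
  if (length(av) != length(bv)) stop("gapped sequences differ in length")
  comp <- av %in% BASES & bv %in% BASES
  n <- sum(comp)
  if (n == 0) stop("no comparable columns")
  a <- av[comp]; b <- bv[comp]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  k2p_from_pq(P, Q, n)
}

k2p_from_pq <- function(P, Q, n) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  valid <- arg1 > 0 && arg2 > 0
  d <- if (valid) -0.5 * log(arg1) - 0.25 * log(arg2) + 0 else NA_real_
  structure(list(P = P, Q = Q, n_comparable = n, d = d, valid = valid),
            class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat(sprintf("K2P: P = %.4f, Q = %.4f over %d columns; d = %s%s\n",
              x$P, x$Q, x$n_comparable,
              ifelse(x$valid, sprintf("%.4f", x$d), "undefined"),
              ifelse(x$valid, "", " (saturated)")))
  invisible(x)
}

#' Pairwise K2P distance matrix
#'
#' Aligns every pair of sequences globally and computes K2P distances.
#' The matrix is symmetric with a zero diagonal; saturated (invalid) pairs
#' are flagged and carry `NA` distances, and their count is recorded.
#'
#' @param records named character vector of sequences, or a data.frame with
#'   `id` and `seq` columns; at least 2 records.
#' @param scoring an [alignment_scoring()] object.
#' @return an object of class `k2p_matrix`: `d` (distance matrix), `valid`
#'   (logical matrix), `P`, `Q`, `n_comparable`, and `n_invalid`.
#' @export
distance_matrix <- function(records, scoring = alignment_scoring()) {
  if (is.data.frame(records)) records <- setNames(records$seq, records$id)
  if (length(records) < 2) stop("need at least 2 records")
  if (is.null(names(records)))
    names(records) <- sprintf("seq%d", seq_along(records))
  cnt <- .c_k2p_counts(unname(records), scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  n_mat <- cnt$comparable
  if (any(n_mat == 0)) stop("a pair has no comparable columns")
  P <- cnt$transitions / n_mat
  Q <- cnt$transversions / n_mat
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  valid <- arg1 > 0 & arg2 > 0
  d <- matrix(NA_real_, nrow(P), ncol(P))
  d[valid] <- -0.5 * log(arg1[valid]) - 0.25 * log(arg2[valid])
  labs <- names(records)
  dimnames(d) <- dimnames(valid) <- dimnames(P) <- dimnames(Q) <-
    dimnames(n_mat) <- list(labs, labs)
  n_invalid <- sum(!valid[upper.tri(valid)])
  structure(list(d = d, valid = valid, P = P, Q = Q, n_comparable = n_mat,
                 n_invalid = n_invalid), class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("K2P distance matrix:", nrow(x$d), "sequences")
  if (x$n_invalid > 0) cat(";", x$n_invalid, "saturated pair(s) excluded")
  cat("\n")
  print(round(x$d, 4))
  invisible(x)
}
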