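# Divergence statistics: the six intra-/inter-specific summary metrics and
# the length/GC composition summaries.

# Collect conspecific and congeneric-heterospecific distance samples from one
# genus-level k2p_matrix. Invalid (saturated) pairs are excluded.
collect_pair_samples <- function(dm, species) {
  n <- nrow(dm$d)
  stopifnot(length(species) == n)
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  same_sp <- species[ut[, 1]] == species[ut[, 2]]
  ok <- dm$valid[upper.tri(dm$valid)]
  list(
    intra = dm$d[upper.tri(dm$d)][same_sp & ok],
    inter = dm$d[upper.tri(dm$d)][!same_sp & ok],
    pairs = ut, same_sp = same_sp, ok = ok)
}

#' Intra-specific divergence metrics
#'
#' From a distance matrix and species labels computes the three
#' intra-specific summaries: the pooled mean over all conspecific pairs
#' (`all_intra`), theta (per-species mean conspecific distance averaged,
#' unweighted, over species with at least 2 records) and the coalescent depth
#' (per-species maximum conspecific distance, averaged the same way).
#' Standard deviations are population-style over the respective samples
#' (pooled pairs for `all_intra`; per-species values for the other two).
#'
#' @param dm a [distance_matrix()] result.
#' @param species character vector of species labels, one per matrix row.
#' @return list of class `intra_metrics` with elements `all_intra`, `theta`,
#'   `coalescent_depth` (each `mean`, `sd`, `n`) and the underlying `samples`.
#'   Metrics are reported as `NA` with `n = 0` when no species has >= 2
#'   records.
#' @export
intra_metrics <- function(dm, species) {
  cs <- collect_pair_samples(dm, species)
  per_species <- lapply(split(seq_along(species), species), function(idx) {
    if (length(idx) < 2) return(NULL)
    sub <- dm$d[idx, idx]
    vv <- dm$valid[idx, idx]
    vals <- sub[upper.tri(sub)][vv[upper.tri(vv)]]
    if (!length(vals)) return(NULL)
    c(mean = mean(vals), max = max(vals))
  })
  per_species <- per_species[!vapply(per_species, is.null, logical(1))]
  sp_means <- vapply(per_species, `[[`, numeric(1), "mean")
  sp_max <- vapply(per_species, `[[`, numeric(1), "max")
  msd <- function(x) list(mean = if (length(x)) mean(x) else NA_real_,
                          sd = sd_pop(x), n = length(x))
  structure(list(all_intra = msd(cs$intra), theta = msd(sp_means),
                 coalescent_depth = msd(sp_max),
                 samples = list(intra_pairs = cs$intra,
                                species_means = sp_means,
                                species_max = sp_max)),
            class = "intra_metrics")
}

#' Inter-specific divergence metrics
#'
#' From a distance matrix with species and genus labels computes the three
#' inter-specific summaries over congeneric heterospecific pairs: the pooled
#' mean (`all_inter`), theta prime (per-genus mean heterospecific distance
#' averaged, unweighted, over genera) and the minimum inter-specific distance
#' (per species, the smallest distance to any congeneric heterospecific
#' sequence, averaged over species).
#'
#' @param dm a [distance_matrix()] result.
#' @param species,genus label vectors, one per matrix row.
#' @return list of class `inter_metrics` with `all_inter`, `theta_prime`,
#'   `min_inter` (each `mean`, `sd`, `n`) and the underlying `samples`.
#' @export
inter_metrics <- function(dm, species, genus) {
  n <- nrow(dm$d)
  stopifnot(length(species) == n, length(genus) == n)
  inter_pairs <- numeric(0)
  genus_means <- numeric(0)
  sp_min <- numeric(0)
  for (g in unique(genus)) {
    idx <- which(genus == g)
    if (length(idx) < 2 || length(unique(species[idx])) < 2) next
    sub <- dm$d[idx, idx, drop = FALSE]
    vv <- dm$valid[idx, idx, drop = FALSE]
    sp <- species[idx]
    hetero <- outer(sp, sp, "!=") & upper.tri(sub) & vv
    vals <- sub[hetero]
    if (!length(vals)) next
    inter_pairs <- c(inter_pairs, vals)
    genus_means <- c(genus_means, mean(vals))
    for (s in unique(sp)) {
      own <- sp == s
      block <- sub[own, !own, drop = FALSE]
      bv <- vv[own, !own, drop = FALSE]
      v <- block[bv]
      if (length(v)) sp_min <- c(sp_min, min(v))
    }
  }
  msd <- function(x) list(mean = if (length(x)) mean(x) else NA_real_,
                          sd = sd_pop(x), n = length(x))
  structure(list(all_inter = msd(inter_pairs), theta_prime = msd(genus_means),
                 min_inter = msd(sp_min),
                 samples = list(inter_pairs = inter_pairs,
                                genus_means = genus_means,
                                species_min = sp_min)),
            class = "inter_metrics")
}

#' Six-metric divergence summary per taxon set
#'
#' Computes, for each taxon set (grouping level), the six divergence
#' statistics over congeneric comparisons: all inter-specific distance, theta
#' prime and minimum inter-specific distance; all intra-specific distance,
#' theta and coalescent depth. Distances are K2P on optimal pairwise global
#' alignments; distance matrices are built per genus (only congeneric pairs
#' enter any metric). Saturated pairs are excluded and counted.
#'
#' @param records data.frame with `id`, `seq`.
#' @param taxonomy data.frame with `id`, `group`, `family`, `genus`,
#'   `species` covering every record.
#' @param group_by taxon-set level: `"group"`, `"family"` or `"genus"`.
#' @param scoring an [alignment_scoring()] object.
#' @return a data.frame of class `divergence_summary`, one row per taxon set,
#'   with `<metric>_mean`, `<metric>_sd` and `<metric>_n` columns for the six
#'   metrics plus counts of genera, species and excluded saturated pairs.
#' @export
divergence_summary <- function(records, taxonomy,
                               group_by = c("group", "family", "genus"),
                               scoring = alignment_scoring()) {
  group_by <- match.arg(group_by)
  tax <- taxonomy[match(records$id, taxonomy$id), ]
  if (any(is.na(tax$species)))
    stop("records without taxonomy row: ",
         paste(records$id[is.na(tax$species)], collapse = ", "))
  out <- lapply(split(seq_len(nrow(records)), tax[[group_by]]), function(ix) {
    intra_pairs <- numeric(0); sp_means <- numeric(0); sp_max <- numeric(0)
    inter_pairs <- numeric(0); genus_means <- numeric(0); sp_min <- numeric(0)
    n_invalid <- 0L
    for (g in unique(tax$genus[ix])) {
      gi <- ix[tax$genus[ix] == g]
      if (length(gi) < 2) next
      dm <- distance_matrix(setNames(records$seq[gi], records$id[gi]),
                            scoring)
      n_invalid <- n_invalid + dm$n_invalid
      im <- intra_metrics(dm, tax$species[gi])
      xm <- inter_metrics(dm, tax$species[gi], tax$genus[gi])
      intra_pairs <- c(intra_pairs, im$samples$intra_pairs)
      sp_means <- c(sp_means, im$samples$species_means)
      sp_max <- c(sp_max, im$samples$species_max)
      inter_pairs <- c(inter_pairs, xm$samples$inter_pairs)
      genus_means <- c(genus_means, xm$samples$genus_means)
      sp_min <- c(sp_min, xm$samples$species_min)
    }
    msd <- function(x) c(mean = if (length(x)) mean(x) else NA_real_,
                         sd = sd_pop(x), n = length(x))
    c(all_inter = msd(inter_pairs), theta_prime = msd(genus_means),
      min_inter = msd(sp_min), all_intra = msd(intra_pairs),
      theta = msd(sp_means), coalescent_depth = msd(sp_max),
      n_genera = length(unique(tax$genus[ix])),
      n_species = length(unique(tax$species[ix])),
      n_invalid_pairs = n_invalid)
  })
  df <- data.frame(taxon_set = names(out), do.call(rbind, out),
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- gsub("\\.", "_", names(df))
  class(df) <- c("divergence_summary", "data.frame")
  df
}

#' Length and GC composition summary per taxon set
#'
#' Mean, median and quartiles of sequence length and GC content per taxon
#' set, the numbers behind the familiar barcode box plots. GC counts G+C over
#' unambiguous (A/C/G/T) positions only.
#'
#' @inheritParams divergence_summary
#' @return a data.frame with one row per taxon set.
#' @export
composition_summary <- function(records, taxonomy,
                                group_by = c("group", "family", "genus")) {
  group_by <- match.arg(group_by)
  tax <- taxonomy[match(records$id, taxonomy$id), ]
  lens <- nchar(records$seq)
  gc <- gc_content(records$seq)
  out <- lapply(split(seq_len(nrow(records)), tax[[group_by]]), function(ix) {
    q_len <- quantile(lens[ix], c(0.25, 0.75), names = FALSE)
    q_gc <- quantile(gc[ix], c(0.25, 0.75), names = FALSE, na.rm = TRUE)
    c(n = length(ix),
      length_mean = mean(lens[ix]), length_median = median(lens[ix]),
      length_q1 = q_len[1], length_q3 = q_len[2],
      gc_mean = mean(gc[ix], na.rm = TRUE),
      gc_median = median(gc[ix], na.rm = TRUE),
      gc_q1 = q_gc[1], gc_q3 = q_gc[2])
  })
  data.frame(taxon_set = names(out), do.call(rbind, out), row.names = NULL,
             stringsAsFactors = FALSE)
}
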