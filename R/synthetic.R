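#' Simulation parameters for synthetic ITS2 datasets
#'
#' Bundles and validates every knob of the dataset generator. The defaults
#' describe a modest multi-family collection whose inter-specific divergence
#' exceeds its intra-specific variation, the regime under which distance-based
#' barcoding is expected to work.
#'
#' Branch lengths are expected substitutions per site under a Kimura
#' two-parameter process. The genealogy is a star-within-star ultrametric
#' tree: within a genus every species ancestor sits at depth `inter_branch`
#' from the genus ancestor, and every sequence at depth `intra_branch` from
#' its species ancestor (the species branch proper is
#' `inter_branch - intra_branch`). Consequently two conspecific sequences are
#' separated by an expected `2 * intra_branch` substitutions per site and two
#' congeneric heterospecific sequences by `2 * inter_branch`, which makes the
#' simulation truth directly commensurable with the K2P estimates of
#' [divergence_summary()].
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_families,genera_per_family,species_per_genus,seqs_per_species
#'   taxonomy shape counts, all >= 1.
#' @param core_length length (nt) of the simulated ITS2 core.
#' @param flank_5_8S_length,flank_28S_length lengths (nt) of the conserved
#'   5.8S-tail and 28S-head anchor segments attached to every record.
#' @param intra_branch,inter_branch root-to-tip depths (expected
#'   substitutions/site) of the species and genus levels; see Details.
#' @param kappa transition/transversion rate ratio of the substitution
#'   process.
#' @param gc_target GC fraction at which ancestral cores are drawn.
#' @param contaminant_rate,short_rate,n_rate,unnamed_rate fractions of
#'   records degraded by [inject_degenerates()]; must sum to at most 1.
#' @param flank_noise per-site substitution probability applied independently
#'   to each record's anchor copies (anchor conservation).
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(seed,
                              n_families = 4L,
                              genera_per_family = 3L,
                              species_per_genus = 3L,
                              seqs_per_species = 3L,
                              core_length = 400L,
                              flank_5_8S_length = 30L,
                              flank_28S_length = 30L,
                              intra_branch = 0.01,
                              inter_branch = 0.2,
                              kappa = 2,
                              gc_target = 0.55,
                              contaminant_rate = 0,
                              short_rate = 0,
                              n_rate = 0,
                              unnamed_rate = 0,
                              flank_noise = 0.02) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' is mandatory and must be a single integer")
  counts <- c(n_families = n_families, genera_per_family = genera_per_family,
              species_per_genus = species_per_genus,
              seqs_per_species = seqs_per_species, core_length = core_length,
              flank_5_8S_length = flank_5_8S_length,
              flank_28S_length = flank_28S_length)
  if (any(counts < 1))
    stop("non-positive count: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  rates <- c(contaminant_rate = contaminant_rate, short_rate = short_rate,
             n_rate = n_rate, unnamed_rate = unnamed_rate,
             flank_noise = flank_noise, gc_target = gc_target)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (intra_branch < 0 || inter_branch < 0 || kappa <= 0)
    stop("branch lengths must be >= 0 and kappa > 0")
  structure(list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    seqs_per_species = as.integer(seqs_per_species),
    core_length = as.integer(core_length),
    flank_5_8S_length = as.integer(flank_5_8S_length),
    flank_28S_length = as.integer(flank_28S_length),
    intra_branch = intra_branch, inter_branch = inter_branch,
    kappa = kappa, gc_target = gc_target,
    contaminant_rate = contaminant_rate, short_rate = short_rate,
    n_rate = n_rate, unnamed_rate = unnamed_rate,
    flank_noise = flank_noise), class = "simulation_params")
}

#' Generate a nested synthetic taxonomy
#'
#' Builds a deterministic group/family/genus/species hierarchy with the shape
#' requested in `params`. Genus names are unique across the dataset and
#' species names unique within each genus.
#'
#' @param params a [simulation_params()] object.
#' @return a data.frame of class `taxonomy_nodes` with one row per species and
#'   columns `group`, `family`, `genus`, `species`.
#' @export
generate_taxonomy <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  nf <- params$n_families; ng <- params$genera_per_family
  ns <- params$species_per_genus
  fam <- rep(sprintf("Family%02d", seq_len(nf)), each = ng * ns)
  gidx <- rep(seq_len(nf * ng), each = ns)
  gen <- sprintf("Genus%03d", gidx)
  sp <- sprintf("%s taxon%02d", gen, rep(seq_len(ns), times = nf * ng))
  structure(data.frame(group = "synthetic", family = fam, genus = gen,
                       species = sp, stringsAsFactors = FALSE),
            class = c("taxonomy_nodes", "data.frame"))
}

# --- Kimura two-parameter simulation -------------------------------------

# Substitution probabilities after branch length t (expected subs/site) under
# K2P with transition/transversion rate ratio kappa. Rates are scaled so the
# total substitution rate is 1 per unit branch length.
k2p_transition_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)  # each of the two transversion targets
}

# Evolve an integer-coded sequence (1=A 2=C 3=G 4=T) for branch length t.
# Transition partners: A<->G (1<->3), C<->T (2<->4).
evolve_seq_int <- function(s, t, kappa) {
  if (t <= 0) return(s)
  pr <- k2p_transition_probs(t, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)
  out <- s
  for (b in 1:4) {
    idx <- which(s == b)
    if (!length(idx)) next
    others <- setdiff(1:4, c(b, ts_partner[b]))
    targets <- c(b, ts_partner[b], others)
    new <- sample(targets, length(idx), replace = TRUE,
                  prob = c(pr["same"], pr["ts"], pr["tv"], pr["tv"]))
    out[idx] <- new
  }
  out
}

random_seq_int <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

int_to_seq <- function(s) paste(BASES[s], collapse = "")
seq_to_int <- function(x) match(strsplit(x, "")[[1]], BASES)

# Substitute each position independently with probability `rate` (uniform
# choice among the three other bases).
noisy_copy_int <- function(s, rate) {
  if (rate <= 0) return(s)
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(1:4, b), 1L),
                     integer(1))
  }
  s
}

#' Simulate flanked ITS2 sequences over a taxonomy
#'
#' Draws one ancestral core per genus at the target GC composition and evolves
#' it down the star-within-star genealogy described in [simulation_params()]
#' under a K2P substitution process. Conserved 5.8S-tail and 28S-head anchors
#' (one canonical copy each per dataset, with independent per-record noise)
#' are attached to every core, and the true core interval is recorded in the
#' ground truth using 0-based half-open coordinates on the raw sequence.
#'
#' @param taxonomy a [generate_taxonomy()] result.
#' @param params a [simulation_params()] object.
#' @return a list of class `its2_dataset` with elements
#'   \describe{
#'   \item{records}{data.frame `id`, `seq` (raw flanked sequences)}
#'   \item{taxonomy}{per-record lineage (`id`, `group`, `family`, `genus`,
#'     `species`)}
#'   \item{ground_truth}{`id`, `core_start`, `core_end`, `reject_reason`,
#'     `contaminant`}
#'   \item{anchors}{canonical anchor sequences plus small gap-free training
#'     alignments for profile building}
#'   \item{fungal}{a [fungal_reference_set()] for contamination screening}
#'   }
#' @export
simulate_sequences <- function(taxonomy, params) {
  stopifnot(inherits(params, "simulation_params"),
            is.data.frame(taxonomy), nrow(taxonomy) >= 1)
  with_seed(params$seed, {
    f58 <- random_seq_int(params$flank_5_8S_length, 0.5)
    f28 <- random_seq_int(params$flank_28S_length, 0.5)
    aln58 <- vapply(1:8, function(i)
      int_to_seq(noisy_copy_int(f58, params$flank_noise)), character(1))
    aln28 <- vapply(1:8, function(i)
      int_to_seq(noisy_copy_int(f28, params$flank_noise)), character(1))

    sp_branch <- max(params$inter_branch - params$intra_branch, 0)
    genera <- unique(taxonomy$genus)
    ids <- character(0); seqs <- character(0)
    tax_rows <- vector("list", 0)
    core_start <- integer(0); core_end <- integer(0)
    counter <- 0L
    for (g in genera) {
      anc <- random_seq_int(params$core_length, params$gc_target)
      sp_rows <- taxonomy[taxonomy$genus == g, , drop = FALSE]
      for (r in seq_len(nrow(sp_rows))) {
        sp_core <- evolve_seq_int(anc, sp_branch, params$kappa)
        for (k in seq_len(params$seqs_per_species)) {
          counter <- counter + 1L
          core <- evolve_seq_int(sp_core, params$intra_branch, params$kappa)
          left <- noisy_copy_int(f58, params$flank_noise)
          right <- noisy_copy_int(f28, params$flank_noise)
          ids <- c(ids, sprintf("seq%05d", counter))
          seqs <- c(seqs, paste0(int_to_seq(left), int_to_seq(core),
                                 int_to_seq(right)))
          tax_rows[[counter]] <- sp_rows[r, , drop = FALSE]
          core_start <- c(core_start, params$flank_5_8S_length)
          core_end <- c(core_end,
                        params$flank_5_8S_length + params$core_length)
        }
      }
    }
    rec_tax <- do.call(rbind, tax_rows)
    rec_tax <- data.frame(id = ids, rec_tax, row.names = NULL,
                          stringsAsFactors = FALSE)
    structure(list(
      records = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
      taxonomy = rec_tax,
      ground_truth = data.frame(id = ids, core_start = core_start,
                                core_end = core_end, reject_reason = "",
                                contaminant = FALSE, stringsAsFactors = FALSE),
      anchors = list(flank_5_8S = int_to_seq(f58), flank_28S = int_to_seq(f28),
                     alignment_5_8S = aln58, alignment_28S = aln28),
      fungal = fungal_reference_set(seed = params$seed,
                                    core_length = min(params$core_length,
                                                      300L)),
      params = params), class = "its2_dataset")
  })
}

#' Synthetic fungal reference pool
#'
#' Generates a small, seeded set of fungal-like decoy references: an
#' independent high-divergence sequence pool sharing a conserved fungal
#' anchor motif. It stands in for a fungal nrITS database during contaminant
#' screening; it is entirely synthetic.
#'
#' @param seed integer seed.
#' @param n_refs number of reference decoys.
#' @param core_length decoy core length (nt).
#' @return list with `refs` (named character vector of reference sequences)
#'   and `motif_alignment` (gap-free alignment of the conserved fungal anchor,
#'   suitable for [build_profile()]).
#' @export
fungal_reference_set <- function(seed, n_refs = 5L, core_length = 300L) {
  with_seed(seed + 90001L, {
    motif <- random_seq_int(32L, 0.5)
    anc <- random_seq_int(core_length, 0.5)
    refs <- vapply(seq_len(n_refs), function(i) {
      core <- evolve_seq_int(anc, 0.05, 2)
      paste0(int_to_seq(noisy_copy_int(motif, 0.02)), int_to_seq(core))
    }, character(1))
    names(refs) <- sprintf("fungal%02d", seq_len(n_refs))
    motif_aln <- vapply(1:6, function(i)
      int_to_seq(noisy_copy_int(motif, 0.02)), character(1))
    list(refs = refs, motif_alignment = motif_aln)
  })
}

#' Inject degenerate records into a simulated dataset
#'
#' Applies the seeded degradation the curation filters target: truncation
#' below 100 nt, >= 3 ambiguous N bases, "sp."/"aff." species labels, and
#' replacement by a divergent fungal decoy. Each record receives at most one
#' alteration and its intended-reject reason is recorded in the ground truth.
#'
#' @param dataset an `its2_dataset` from [simulate_sequences()].
#' @param params the [simulation_params()] carrying the degradation rates.
#' @return the modified `its2_dataset`.
#' @export
inject_degenerates <- function(dataset, params) {
  stopifnot(inherits(dataset, "its2_dataset"),
            inherits(params, "simulation_params"))
  total <- params$short_rate + params$n_rate + params$unnamed_rate +
    params$contaminant_rate
  if (total > 1) stop("degeneration rates sum above 1 (", total, ")")
  if (total == 0) return(dataset)
  with_seed(params$seed + 1L, {
    n <- nrow(dataset$records)
    u <- runif(n)
    kind <- rep("none", n)
    kind[u < params$short_rate] <- "short"
    kind[u >= params$short_rate &
           u < params$short_rate + params$n_rate] <- "ambiguous"
    kind[u >= params$short_rate + params$n_rate &
           u < params$short_rate + params$n_rate +
             params$unnamed_rate] <- "unnamed"
    kind[u >= params$short_rate + params$n_rate + params$unnamed_rate &
           u < total] <- "contaminant"

    for (i in which(kind == "short")) {
      len <- sample(50:99, 1L)
      dataset$records$seq[i] <- substr(dataset$records$seq[i], 1, len)
      dataset$ground_truth$core_start[i] <-
        min(dataset$ground_truth$core_start[i], len)
      dataset$ground_truth$core_end[i] <-
        min(dataset$ground_truth$core_end[i], len)
    }
    for (i in which(kind == "ambiguous")) {
      s <- strsplit(dataset$records$seq[i], "")[[1]]
      pos <- sample(length(s), 3L)
      s[pos] <- "N"
      dataset$records$seq[i] <- paste(s, collapse = "")
    }
    for (i in which(kind == "unnamed")) {
      tok <- sample(c("sp.", "aff."), 1L)
      dataset$taxonomy$species[i] <-
        paste(dataset$taxonomy$genus[i], tok)
    }
    decoys <- which(kind == "contaminant")
    if (length(decoys)) {
      pool <- dataset$fungal$refs
      for (i in decoys) {
        ref <- pool[[sample(length(pool), 1L)]]
        decoy <- int_to_seq(evolve_seq_int(seq_to_int(ref), 0.05,
                                           params$kappa))
        dataset$records$seq[i] <- decoy
        dataset$ground_truth$core_start[i] <- 0L
        dataset$ground_truth$core_end[i] <- nchar(decoy)
      }
    }
    altered <- kind != "none"
    dataset$ground_truth$reject_reason[altered] <- kind[altered]
    dataset$ground_truth$contaminant <- kind == "contaminant"
    dataset
  })
}

#' Write a simulated dataset to disk
#'
#' Serializes raw sequences (FASTA), the taxonomy table and ground truth
#' (TSV), plus the anchor training alignments and the fungal reference pool.
#'
#' @param dataset an `its2_dataset`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "its2_dataset"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    raw = file.path(out_dir, "raw.fasta"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.tsv"),
    model58 = file.path(out_dir, "anchor_5_8S_alignment.fasta"),
    model28 = file.path(out_dir, "anchor_28S_alignment.fasta"),
    fungal_refs = file.path(out_dir, "fungal_refs.fasta"),
    fungal_motif = file.path(out_dir, "fungal_motif_alignment.fasta"))
  write_fasta(dataset$records$id, dataset$records$seq, paths["raw"])
  write_tsv(dataset$taxonomy[, c("id", "group", "family", "genus", "species")],
            paths["taxonomy"])
  write_tsv(dataset$ground_truth, paths["ground_truth"])
  a <- dataset$anchors
  write_fasta(sprintf("anchor58_%d", seq_along(a$alignment_5_8S)),
              a$alignment_5_8S, paths["model58"])
  write_fasta(sprintf("anchor28_%d", seq_along(a$alignment_28S)),
              a$alignment_28S, paths["model28"])
  write_fasta(names(dataset$fungal$refs), dataset$fungal$refs,
              paths["fungal_refs"])
  write_fasta(sprintf("fmotif_%d", seq_along(dataset$fungal$motif_alignment)),
              dataset$fungal$motif_alignment, paths["fungal_motif"])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir the dataset directory.
#' @return a list with `records`, `taxonomy` and `ground_truth` data.frames.
#' @export
read_dataset <- function(dir) {
  records <- read_fasta(file.path(dir, "raw.fasta"))[, c("id", "seq")]
  taxonomy <- read_tsv(file.path(dir, "taxonomy.tsv"))
  gt <- read_tsv(file.path(dir, "ground_truth.tsv"))
  if (nrow(gt)) {
    gt$reject_reason <- ifelse(is.na(gt$reject_reason), "",
                               as.character(gt$reject_reason))
    gt$contaminant <- as.logical(gt$contaminant)
  }
  list(records = records, taxonomy = taxonomy, ground_truth = gt)
}
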