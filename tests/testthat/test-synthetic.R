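test_that("taxonomy generation yields the requested shape deterministically", {
  p <- simulation_params(seed = 1, n_families = 1, genera_per_family = 1,
                         species_per_genus = 2)
  tax <- generate_taxonomy(p)
  expect_equal(nrow(tax), 2)
  expect_equal(length(unique(tax$genus)), 1)

  p2 <- simulation_params(seed = 1, n_families = 2, genera_per_family = 3,
                          species_per_genus = 4)
  tax2 <- generate_taxonomy(p2)
  expect_equal(nrow(tax2), 24)
  expect_equal(length(unique(tax2$genus)), 6)
  # species unique within genus, genus names globally unique
  expect_false(any(duplicated(tax2$species)))
  expect_equal(length(unique(paste(tax2$family, tax2$genus))),
               length(unique(tax2$genus)))
  expect_identical(tax2, generate_taxonomy(p2))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(seed = 1, n_families = 0), "non-positive")
  expect_error(simulation_params(seed = 1, short_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(), "mandatory")
})

test_that("sequence simulation is seeded and respects the zero-branch case", {
  p <- simulation_params(seed = 7, n_families = 1, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 3,
                         core_length = 120, intra_branch = 0,
                         flank_noise = 0)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  expect_equal(nrow(ds$records), 12)
  # intra_branch = 0: all conspecific sequences identical
  for (sp in unique(ds$taxonomy$species)) {
    seqs <- ds$records$seq[ds$taxonomy$species == sp]
    expect_equal(length(unique(seqs)), 1)
  }
  ds2 <- simulate_sequences(generate_taxonomy(p), p)
  expect_identical(ds$records, ds2$records)
})

test_that("ground truth intervals delimit the planted core", {
  p <- simulation_params(seed = 2, n_families = 1, genera_per_family = 1,
                         species_per_genus = 2, seqs_per_species = 2,
                         core_length = 150)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  gt <- ds$ground_truth
  expect_true(all(gt$core_start == p$flank_5_8S_length))
  expect_true(all(gt$core_end == p$flank_5_8S_length + p$core_length))
  expect_true(all(gt$core_end <= nchar(ds$records$seq)))
  expect_equal(anyDuplicated(gt$id), 0)
  expect_equal(sort(gt$id), sort(ds$records$id))
})

test_that("realized core GC composition tracks the target", {
  p <- simulation_params(seed = 11, n_families = 2, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 2,
                         core_length = 400, gc_target = 0.55)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  cores <- substr(ds$records$seq, ds$ground_truth$core_start + 1,
                  ds$ground_truth$core_end)
  expect_lt(abs(mean(gc_content(cores)) - 0.55), 0.03)
})

test_that("K2P estimator recovers the simulated branch length", {
  # two sequences separated by total branch t: mean K2P within 3 SE of t
  t_total <- 0.3
  p <- simulation_params(seed = 99, n_families = 1, genera_per_family = 1,
                         species_per_genus = 2, seqs_per_species = 1,
                         core_length = 300, intra_branch = 0,
                         inter_branch = t_total / 2)
  d <- vapply(1:200, function(s) {
    ps <- p; ps$seed <- 1000L + s
    ds <- simulate_sequences(generate_taxonomy(ps), ps)
    cores <- substr(ds$records$seq, ds$ground_truth$core_start + 1,
                    ds$ground_truth$core_end)
    k2p_distance(align_pair(cores[1], cores[2]))$d
  }, numeric(1))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - t_total), 3 * se)
})

test_that("degenerate injection is seeded, counted and reversible at rate 0", {
  p <- simulation_params(seed = 21, n_families = 2, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 2,
                         core_length = 150)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  expect_identical(inject_degenerates(ds, p), ds)  # all rates 0

  p_short <- p; p_short$short_rate <- 1
  short <- inject_degenerates(ds, p_short)
  expect_true(all(nchar(short$records$seq) < 100))
  expect_true(all(short$ground_truth$reject_reason == "short"))

  p_n <- p; p_n$n_rate <- 0.5
  dn <- inject_degenerates(ds, p_n)
  tagged <- sum(dn$ground_truth$reject_reason == "ambiguous")
  # replay the seeded draw (the generator derives its stream from seed + 1)
  expected <- with_seed_replay(p$seed + 1L, nrow(ds$records), 0.5)
  expect_equal(tagged, expected)
  expect_identical(dn$ground_truth, inject_degenerates(ds, p_n)$ground_truth)
  # altered records carry >= 3 Ns
  amb <- dn$ground_truth$reject_reason == "ambiguous"
  expect_true(all(vapply(dn$records$seq[amb], function(s)
    nchar(gsub("[^N]", "", s)) >= 3, logical(1))))

  p_bad <- p; p_bad$short_rate <- 0.6; p_bad$n_rate <- 0.6
  expect_error(inject_degenerates(ds, p_bad), "sum above 1")
})

test_that("unnamed and contaminant injections are recorded in ground truth", {
  p <- simulation_params(seed = 31, n_families = 2, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 3,
                         core_length = 150, unnamed_rate = 0.3,
                         contaminant_rate = 0.3)
  ds <- inject_degenerates(simulate_sequences(generate_taxonomy(p), p), p)
  gt <- ds$ground_truth
  unnamed <- gt$reject_reason == "unnamed"
  expect_true(any(unnamed))
  expect_true(all(grepl("sp\\.|aff\\.", ds$taxonomy$species[unnamed])))
  expect_identical(gt$contaminant, gt$reject_reason == "contaminant")
  # reasons partition the degenerate set: one reason per altered record
  expect_true(all(gt$reject_reason %in%
                    c("", "short", "ambiguous", "unnamed", "contaminant")))
})

test_that("dataset writing round-trips through disk", {
  p <- simulation_params(seed = 41, n_families = 1, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 1,
                         core_length = 120, n_rate = 0.25)
  ds <- inject_degenerates(simulate_sequences(generate_taxonomy(p), p), p)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$records, ds$records)
  expect_equal(back$taxonomy, ds$taxonomy)
  expect_equal(back$ground_truth, ds$ground_truth)

  fa <- read_fasta(file.path(dir, "raw.fasta"))
  expect_equal(nrow(fa), nrow(ds$records))
})

test_that("an empty record set still writes valid headed files", {
  p <- simulation_params(seed = 5, n_families = 1, genera_per_family = 1,
                         species_per_genus = 2, seqs_per_species = 1,
                         core_length = 120)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  ds$records <- ds$records[0, ]
  ds$taxonomy <- ds$taxonomy[0, ]
  ds$ground_truth <- ds$ground_truth[0, ]
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "raw.fasta")))
  tax <- its2eval:::read_tsv(file.path(dir, "taxonomy.tsv"))
  expect_equal(nrow(tax), 0)
  expect_equal(names(tax), c("id", "group", "family", "genus", "species"))
})
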