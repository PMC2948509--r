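make_filter_fixture <- function() {
  clean <- strrep("ACGT", 50)                       # 200 nt, no Ns
  recs <- data.frame(
    id = paste0("r", 1:6),
    seq = c(clean, clean, strrep("AC", 45),          # r3: 90 nt
            paste0("ANNNCG", strrep("ACGT", 40)),    # r4: 3 Ns
            clean, clean),
    stringsAsFactors = FALSE)
  tax <- data.frame(
    id = paste0("r", 1:6), group = "plants", family = "Cyperaceae",
    genus = c("Carex", "Carex", "Carex", "Carex", "Carex", "Uncinia"),
    species = c("Carex firma", "Carex humilis", "Carex alba",
                "Carex nigra", "Carex sp.", "Uncinia sola"),
    stringsAsFactors = FALSE)
  list(records = recs, taxonomy = tax)
}

test_that("the filters reject each degenerate record for its first failure", {
  fx <- make_filter_fixture()
  out <- apply_filters(fx$records, fx$taxonomy)
  expect_equal(out$kept$id, c("r1", "r2"))
  expect_equal(setNames(out$rejected$reason, out$rejected$id),
               c(r3 = "short", r4 = "ambiguous", r5 = "unnamed",
                 r6 = "monotypic_genus"))
})

test_that("filter boundaries are inclusive: 100 nt and 2 Ns are kept", {
  seq100 <- paste0("NN", strrep("ACGT", 24), "AC")  # exactly 100 nt, 2 Ns
  expect_equal(nchar(seq100), 100)
  recs <- data.frame(id = c("a", "b"), seq = c(seq100, seq100),
                     stringsAsFactors = FALSE)
  tax <- data.frame(id = c("a", "b"), group = "g", family = "f",
                    genus = "Carex",
                    species = c("Carex firma", "Carex humilis"),
                    stringsAsFactors = FALSE)
  out <- apply_filters(recs, tax)
  expect_equal(out$kept$id, c("a", "b"))
  expect_equal(nrow(out$rejected), 0)
})

test_that("filtering partitions, is idempotent and order-invariant", {
  fx <- make_filter_fixture()
  out <- apply_filters(fx$records, fx$taxonomy)
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(fx$records))

  again <- apply_filters(out$kept, fx$taxonomy)
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$rejected), 0)

  set.seed(77)
  perm <- sample(nrow(fx$records))
  shuffled <- apply_filters(fx$records[perm, ], fx$taxonomy)
  expect_equal(sort(shuffled$kept$id), sort(out$kept$id))
  expect_equal(shuffled$rejected[order(shuffled$rejected$id), ],
               out$rejected[order(out$rejected$id), ],
               ignore_attr = TRUE)

  empty <- apply_filters(fx$records[0, ], fx$taxonomy)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)

  expect_error(apply_filters(data.frame(id = "zz", seq = strrep("ACGT", 50)),
                             fx$taxonomy), "zz")
})

test_that("genus occupancy is recounted on the post-filter survivor set", {
  # GenusB has 2 species, but one fails the length filter, leaving a
  # monotypic survivor set -> both survivors of GenusB must go
  recs <- data.frame(id = c("a", "b", "c", "d", "e"),
                     seq = c(strrep("ACGT", 50), strrep("ACGT", 50),
                             strrep("ACGT", 50), strrep("ACGT", 50),
                             strrep("AC", 20)),
                     stringsAsFactors = FALSE)
  tax <- data.frame(id = c("a", "b", "c", "d", "e"), group = "g",
                    family = "f",
                    genus = c("GenusA", "GenusA", "GenusB", "GenusB",
                              "GenusB"),
                    species = c("GenusA one", "GenusA two", "GenusB one",
                                "GenusB one", "GenusB two"),
                    stringsAsFactors = FALSE)
  out <- apply_filters(recs, tax)
  expect_equal(out$kept$id, c("a", "b"))
  expect_equal(setNames(out$rejected$reason, out$rejected$id),
               c(c = "monotypic_genus", d = "monotypic_genus", e = "short"))
  # brute-force recount agrees
  surv <- tax[tax$id %in% c("a", "b", "c", "d"), ]
  occ <- tapply(surv$species, surv$genus, function(s) length(unique(s)))
  expect_equal(unname(occ["GenusB"]), 1)
})

test_that("fungal screening flags the planted decoy on both routes", {
  p <- simulation_params(seed = 51, n_families = 1, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 1,
                         core_length = 200)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  fset <- ds$fungal
  fp <- build_profile(fset$motif_alignment)
  decoy <- fset$refs[[2]]
  recs <- rbind(ds$records, data.frame(id = "decoy", seq = decoy))
  flags <- screen_fungal(recs, fp, fset$refs)
  expect_equal(flags$id[flags$suspect_fungal_hmm], "decoy")
  expect_equal(flags$id[flags$suspect_fungal_blast], "decoy")

  # identity threshold 1.0 flags only exact matches
  cfg <- curation_config(fungal_min_identity = 1.0)
  strict <- screen_fungal(recs, NULL, fset$refs, cfg)
  expect_equal(strict$id[strict$suspect_fungal_blast], "decoy")

  empty <- screen_fungal(recs[0, ], fp, fset$refs)
  expect_equal(nrow(empty), 0)
  expect_warning(screen_fungal(recs[1:2, ], fp, character(0)),
                 "empty fungal reference")
})

test_that("species consensus follows majority rule with IUPAC ties", {
  expect_equal(species_consensus("ACGTACGT"), "ACGTACGT")
  expect_equal(species_consensus(c("ACGT", "ACGT", "ACTT")), "ACGT")
  expect_equal(species_consensus(c("ACGT", "ACTT")), "ACKT")
  # an indel in the minority sequence is absorbed by the majority
  expect_equal(species_consensus(c("ACGTACGT", "ACGTACGT", "ACGACGT")),
               "ACGTACGT")
})

test_that("the reference database assembles, serializes and reloads", {
  p <- simulation_params(seed = 61, n_families = 1, genera_per_family = 1,
                         species_per_genus = 3, seqs_per_species = 2,
                         core_length = 150)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  db <- build_reference_db(ds$records, ds$taxonomy)
  expect_s3_class(db, "reference_db")
  expect_equal(nrow(db$records), 6)
  expect_equal(nrow(db$consensus), 3)
  expect_true(all(db$provenance$decision[db$provenance$id %in%
                                           db$records$id] == "kept"))

  dir <- withr::local_tempdir()
  write_reference_db(db, dir)
  back <- read_reference_db(dir)
  expect_equal(back$records, db$records)
  expect_equal(back$consensus, db$consensus)
  expect_equal(back$taxonomy, db$taxonomy)
  expect_equal(back$provenance, db$provenance)
})

test_that("a flagged fungal decoy can be dropped with full provenance", {
  p <- simulation_params(seed = 72, n_families = 1, genera_per_family = 2,
                         species_per_genus = 2, seqs_per_species = 2,
                         core_length = 200, contaminant_rate = 0.2)
  ds <- inject_degenerates(simulate_sequences(generate_taxonomy(p), p), p)
  contaminated <- ds$ground_truth$id[ds$ground_truth$contaminant]
  expect_gte(length(contaminated), 1)
  fp <- build_profile(ds$fungal$motif_alignment)
  cfg <- curation_config(drop_fungal = TRUE)
  db <- build_reference_db(ds$records, ds$taxonomy, cfg,
                           fungal_profile = fp, fungal_refs = ds$fungal$refs)
  expect_false(any(contaminated %in% db$records$id))
  prov <- db$provenance
  expect_true(all(grepl("fungal", prov$reason[prov$id %in% contaminated])))

  expect_error(build_reference_db(ds$records[0, ], ds$taxonomy),
               "empty reference database")
})
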