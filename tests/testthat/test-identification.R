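small_db <- function(seed = 501, n_fam = 1, n_gen = 2, n_sp = 2, n_seq = 2,
                     core = 120) {
  p <- simulation_params(seed = seed, n_families = n_fam,
                         genera_per_family = n_gen, species_per_genus = n_sp,
                         seqs_per_species = n_seq, core_length = core)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  make_ref_db(ds$records, ds$taxonomy)
}

test_that("a query identical to a database record is uniquely top-ranked", {
  db <- small_db()
  q <- db$records$seq[3]
  hits <- similarity_search(q, db)
  expect_equal(hits$subject_id[1], db$records$id[3])
  expect_equal(hits$score[1], nchar(q))  # perfect self-match score
  expect_equal(sum(hits$rank == 1), 1)
  expect_error(similarity_search(q, db, exclude = db$records$id),
               "empty after exclusion")
})

test_that("identical subjects share rank 1", {
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = c(strrep("ACGT", 20), strrep("ACGT", 20),
                             strrep("TTAA", 20)),
                     stringsAsFactors = FALSE)
  hits <- similarity_search(strrep("ACGT", 20), recs)
  expect_equal(hits$rank, c(1L, 1L, 3L))
  expect_equal(hits$subject_id[1:2], c("a", "b"))  # id tiebreak, sorted
})

test_that("the k-mer pre-screen never changes the ranking of real hits", {
  db <- small_db(seed = 502)
  for (i in c(1, 4, 7)) {
    plain <- similarity_search(db$records$seq[i], db,
                               exclude = db$records$id[i])
    screened <- similarity_search(db$records$seq[i], db,
                                  exclude = db$records$id[i],
                                  use_kmer_filter = TRUE)
    expect_equal(screened$subject_id[screened$rank == 1],
                 plain$subject_id[plain$rank == 1])
  }
})

test_that("top-hit identification matches the exhaustive oracle", {
  set.seed(503)
  for (rep in 1:4) {
    db <- small_db(seed = 510 + rep, n_gen = 3, n_sp = 2, n_seq = 2,
                   core = 100)
    got <- identify_batch(db$records[, c("id", "seq")], db)
    want <- oracle_identify(db$records[, c("id", "seq")], db$records,
                            db$taxonomy)
    expect_equal(got$status_species, want$status_species)
    expect_equal(got$status_genus, want$status_genus)
  }
})

test_that("leave-one-out never lets a query match its own record", {
  db <- small_db(seed = 504)
  for (i in seq_len(nrow(db$records))) {
    hits <- similarity_search(db$records$seq[i], db,
                              exclude = db$records$id[i])
    expect_false(db$records$id[i] %in% hits$subject_id)
  }
  # without leave-one-out every query trivially self-matches
  res <- identify_batch(db$records[, c("id", "seq")], db,
                        leave_one_out = FALSE)
  expect_true(all(res$status_species == "correct"))
})

test_that("shared sequences force species ambiguity but genus resolution", {
  shared <- strrep("ACGTTGCA", 15)
  other <- strrep("GGATCCAA", 15)
  # two species of one genus share an identical sequence equal to the query
  recs <- data.frame(id = paste0("s", 1:5),
                     seq = c(shared, shared, shared, other, other),
                     stringsAsFactors = FALSE)
  tax <- data.frame(id = paste0("s", 1:5), group = "g", family = "f",
                    genus = c("GA", "GA", "GA", "GB", "GB"),
                    species = c("GA one", "GA one", "GA two", "GB one",
                                "GB two"),
                    stringsAsFactors = FALSE)
  db <- make_ref_db(recs, tax)
  r <- blast1_identify(list(id = "s1", seq = shared), db)
  expect_equal(r$status_species, "ambiguous")
  expect_true(is.na(r$assigned_species))
  expect_equal(r$status_genus, "correct")    # tie confined to one genus
  expect_equal(sort(r$top_species), c("GA one", "GA two"))
})

test_that("an adversarial intra > inter fixture yields incorrect status", {
  base <- strsplit(strrep("ACGT", 30), "")[[1]]
  mutate <- function(s, pos, to) { s[pos] <- to; paste(s, collapse = "") }
  # query far from its conspecific, close to a heterospecific
  recs <- data.frame(
    id = c("q", "own", "near"),
    seq = c(paste(base, collapse = ""),
            mutate(base, c(3, 9, 17, 25, 33, 41), "T"),
            mutate(base, 5, "T")),
    stringsAsFactors = FALSE)
  tax <- data.frame(id = c("q", "own", "near"), group = "g", family = "f",
                    genus = "G",
                    species = c("G alpha", "G alpha", "G beta"),
                    stringsAsFactors = FALSE)
  db <- make_ref_db(recs, tax)
  r <- blast1_identify(recs[1, ], db)
  expect_equal(r$assigned_species, "G beta")
  expect_equal(r$status_species, "incorrect")
  expect_equal(r$status_genus, "correct")
})

test_that("success reports aggregate percentages per group and level", {
  db <- small_db(seed = 505, n_fam = 2, n_gen = 2, n_sp = 2, n_seq = 2,
                 core = 150)
  res <- identify_batch(db$records[, c("id", "seq")], db)
  sp <- evaluate_success(db$records[, c("id", "seq")], db, results = res,
                         group_by = "family", level = "species")
  gn <- evaluate_success(db$records[, c("id", "seq")], db, results = res,
                         group_by = "family", level = "genus")
  expect_equal(nrow(sp), 2)
  expect_equal(sp$pct_correct + sp$pct_ambiguous + sp$pct_incorrect,
               rep(100, 2))
  expect_true(all(sp$n_queries >= 1))
  # genus-level success dominates species-level success
  expect_true(all(gn$pct_correct >= sp$pct_correct))

  # single correct query gives a 100/0 row
  one <- evaluate_success(db$records[1, c("id", "seq")], db,
                          results = res[1, , drop = FALSE],
                          group_by = "genus", level = "species")
  expect_equal(one$n_queries, 1)
  expect_true(one$pct_correct %in% c(0, 100))

  expect_error(evaluate_success(data.frame(id = "ghost", seq = "ACGT"), db),
               "taxonomy universe")
})

test_that("collapsed species degenerate to full ambiguity at species level", {
  p <- simulation_params(seed = 506, n_families = 1, genera_per_family = 2,
                         species_per_genus = 3, seqs_per_species = 2,
                         core_length = 120, intra_branch = 0,
                         inter_branch = 0, flank_noise = 0)
  ds <- simulate_sequences(generate_taxonomy(p), p)
  db <- make_ref_db(ds$records, ds$taxonomy)
  res <- identify_batch(db$records[, c("id", "seq")], db)
  expect_true(all(res$status_species == "ambiguous"))
  expect_true(all(res$status_genus == "correct"))

  folded <- evaluate_success(db$records[, c("id", "seq")], db, results = res,
                             level = "species",
                             fold_incorrect_into_ambiguous = TRUE)
  expect_equal(folded$pct_ambiguous, 100)
  expect_equal(folded$pct_incorrect, 0)
})

test_that("reports are deterministic and independent of record order", {
  db <- small_db(seed = 507)
  q <- db$records[, c("id", "seq")]
  r1 <- evaluate_success(q, db, level = "species")
  set.seed(1)
  perm <- sample(nrow(q))
  db2 <- db
  db2$records <- db2$records[perm, ]
  db2$taxonomy <- db2$taxonomy[perm, ]
  r2 <- evaluate_success(q, db2, level = "species")
  expect_equal(as.data.frame(r1), as.data.frame(r2), ignore_attr = TRUE)
})
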