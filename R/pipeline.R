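#' Pipeline configuration
#'
#' Bundles the stage toggles and the per-stage parameter blocks of the full
#' evaluation workflow (simulate, annotate, curate, divergence, identify,
#' report). The global seed drives the simulation and every calibration.
#'
#' @param seed global integer seed.
#' @param simulation a [simulation_params()]; defaults to
#'   `simulation_params(seed)`.
#' @param curation a [curation_config()].
#' @param scoring an [alignment_scoring()].
#' @param max_evalue anchor-acceptance E-value threshold for annotation.
#' @param group_by taxon-set level for the divergence and success summaries.
#' @param leave_one_out identification protocol flag.
#' @param stages named logical list toggling `simulate`, `annotate`,
#'   `curate`, `divergence`, `identify`, `report`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            simulation = simulation_params(seed),
                            curation = curation_config(),
                            scoring = alignment_scoring(),
                            max_evalue = 1.0,
                            group_by = "group",
                            leave_one_out = TRUE,
                            stages = list()) {
  st <- list(simulate = TRUE, annotate = TRUE, curate = TRUE,
             divergence = TRUE, identify = TRUE, report = TRUE)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), simulation = simulation,
                 curation = curation, scoring = scoring,
                 max_evalue = max_evalue, group_by = group_by,
                 leave_one_out = leave_one_out, stages = st),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full evaluation pipeline
#'
#' Executes the stages in fixed order — simulate, annotate, curate,
#' divergence, identify, report — writing each stage's outputs under
#' `out_dir` and recording every output file with its MD5 hash in a run
#' manifest. Re-running with an identical configuration reproduces identical
#' outputs. When the curation stage is disabled, divergence and
#' identification consume the trimmed (uncurated) sequences and the manifest
#' records the skip.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return `out_dir` invisibly; side effect: stage outputs, `manifest.tsv`
#'   and `config.yaml` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- config$stages
  log <- data.frame(stage = character(0), note = character(0),
                    stringsAsFactors = FALSE)
  note <- function(stage, msg) {
    log <<- rbind(log, data.frame(stage = stage, note = msg,
                                  stringsAsFactors = FALSE))
  }

  dataset <- NULL
  if (st$simulate) {
    run_stage("simulate", {
      taxonomy <- generate_taxonomy(config$simulation)
      dataset <- simulate_sequences(taxonomy, config$simulation)
      dataset <- inject_degenerates(dataset, config$simulation)
      write_dataset(dataset, out_dir)
      note("simulate", sprintf("records=%d species=%d",
                               nrow(dataset$records),
                               length(unique(dataset$taxonomy$species))))
    })
  } else {
    run_stage("simulate", {
      dataset <- read_dataset(out_dir)
      note("simulate", "skipped (dataset loaded from run directory)")
    })
  }

  trimmed_records <- NULL
  if (st$annotate) {
    run_stage("annotate", {
      m58 <- build_profile(file.path(out_dir, "anchor_5_8S_alignment.fasta"))
      m28 <- build_profile(file.path(out_dir, "anchor_28S_alignment.fasta"))
      batch <- annotate_batch(dataset$records, m58, m28,
                              max_evalue = config$max_evalue,
                              calib_seed = config$seed)
      write_tsv(batch$results, file.path(out_dir, "annotation.tsv"))
      write_trimmed_fasta(batch, file.path(out_dir, "trimmed.fasta"))
      trimmed_records <- data.frame(id = names(batch$trimmed),
                                     seq = unname(batch$trimmed),
                                     stringsAsFactors = FALSE)
      note("annotate", sprintf("input=%d annotated=%d", nrow(dataset$records),
                               nrow(trimmed_records)))
    })
  } else {
    trimmed_records <- dataset$records
    note("annotate", "skipped (raw sequences passed through)")
  }

  db <- NULL
  analysis_records <- trimmed_records
  if (st$curate) {
    run_stage("curate", {
      fungal <- dataset$fungal
      fp <- if (!is.null(fungal)) build_profile(fungal$motif_alignment)
            else NULL
      fr <- if (!is.null(fungal)) fungal$refs else character(0)
      db <- build_reference_db(trimmed_records, dataset$taxonomy,
                                config$curation, fungal_profile = fp,
                                fungal_refs = fr, scoring = config$scoring)
      write_reference_db(db, file.path(out_dir, "refdb"))
      analysis_records <- db$records[, c("id", "seq")]
      note("curate", sprintf("input=%d kept=%d rejected=%d",
                             nrow(trimmed_records), nrow(db$records),
                             sum(db$provenance$decision == "rejected")))
    })
  } else {
    note("curate", "skipped (divergence consumes trimmed sequences)")
  }

  if (st$divergence) {
    run_stage("divergence", {
      dv <- divergence_summary(analysis_records, dataset$taxonomy,
                               group_by = config$group_by,
                               scoring = config$scoring)
      cp <- composition_summary(analysis_records, dataset$taxonomy,
                                group_by = config$group_by)
      write_tsv(dv, file.path(out_dir, "divergence_summary.tsv"))
      write_tsv(cp, file.path(out_dir, "composition_summary.tsv"))
      note("divergence", sprintf("taxon_sets=%d", nrow(dv)))
    })
  }

  if (st$identify) {
    run_stage("identify", {
      qdb <- if (!is.null(db)) db else
        structure(list(records = data.frame(analysis_records,
                         dataset$taxonomy[match(analysis_records$id,
                                                dataset$taxonomy$id),
                                          c("group", "family", "genus",
                                            "species")],
                         row.names = NULL, stringsAsFactors = FALSE),
                       taxonomy = dataset$taxonomy,
                       consensus = NULL, provenance = NULL,
                       config = config$curation),
                  class = "reference_db")
      ids <- identify_batch(qdb$records[, c("id", "seq")], qdb,
                            leave_one_out = config$leave_one_out,
                            scoring = config$scoring)
      sp_rep <- evaluate_success(qdb$records[, c("id", "seq")], qdb,
                                 group_by = config$group_by,
                                 level = "species", results = ids)
      gn_rep <- evaluate_success(qdb$records[, c("id", "seq")], qdb,
                                 group_by = config$group_by,
                                 level = "genus", results = ids)
      write_tsv(ids, file.path(out_dir, "identification.tsv"))
      write_tsv(rbind(as.data.frame(sp_rep), as.data.frame(gn_rep)),
                file.path(out_dir, "success_report.tsv"))
      note("identify", sprintf("queries=%d", nrow(ids)))
    })
  }

  write_tsv(log, file.path(out_dir, "stage_log.tsv"))
  writeLines(yaml::as.yaml(config_to_list(config)),
             file.path(out_dir, "config.yaml"))

  if (st$report) run_stage("report", make_report(out_dir))

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

config_to_list <- function(config) {
  rapply(unclass(config), f = identity, how = "replace")
}

#' Assemble a run report
#'
#' Collects the stage outputs of a pipeline run directory into one markdown
#' document with four sections: composition summaries, the six-metric
#' divergence table, the taxon-set success table, and per-genus breakdowns.
#' Numbers are copied verbatim from the stage TSVs; nothing is recomputed.
#' Missing stage outputs lead to an omitted section with a notice.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir) {
  path <- file.path(run_dir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  tsv_block <- function(f) {
    df <- read_tsv(f)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(r, collapse = "\t")))
  }
  section <- function(title, file, note) {
    w(paste("##", title), "")
    f <- file.path(run_dir, file)
    if (file.exists(f)) w(tsv_block(f), "") else w(paste("*", note, "*"), "")
  }
  w("# ITS2 barcode evaluation report", "")
  section("Sequence length and GC content", "composition_summary.tsv",
          "composition summary missing (divergence stage not run)")
  section("Intra- and inter-specific divergence", "divergence_summary.tsv",
          "divergence summary missing (divergence stage not run)")
  section("Identification success by taxon set", "success_report.tsv",
          "success report missing (identification stage not run)")
  if (file.exists(file.path(run_dir, "identification.tsv"))) {
    w("## Per-query identifications", "")
    w(tsv_block(file.path(run_dir, "identification.tsv")), "")
  } else {
    w("## Per-query identifications", "",
      "* identification results missing (identification stage not run) *", "")
  }
  invisible(path)
}
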