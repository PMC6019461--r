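# Pipeline orchestration and the command-line interface.
#
# The pipeline chains preprocess -> MAF correction -> annotation ->
# clonotyping -> diversity -> evaluation over one or more replicate
# libraries, writing stage artifacts plus a run manifest (config echo,
# package version, seeds, input checksums) so every run is reproducible
# from its manifest alone.

#' Run the MAF analysis pipeline
#'
#' @param reads data.frame of reads (read_id, sequence, quality, optional
#'   replicate_id) or a FASTQ path
#' @param db a `germline_db`
#' @param layout a `maf_layout`
#' @param standards optional `spikein_set` (enables spike-in evaluation)
#' @param manifest optional named expected-frequency vector for evaluation
#' @param out_dir optional output directory for stage artifacts
#' @param min_mean_q,length_range quality/length filter settings
#' @param fid_length,rid_length read-layout UID lengths
#' @param merge_near_rids absorb 1-mismatch singleton RIDs
#' @param min_reads_for_consensus UID consensus threshold
#' @param similarity_threshold,linkage clonotyping settings
#' @param config optional list echoed into the run manifest
#' @return list of class `maf_run`: parsed, corrected, annotated,
#'   clonotypes, incidence, diversity, evaluation, manifest
#' @export
run_pipeline <- function(reads, db, layout, standards = NULL,
                         manifest = NULL, out_dir = NULL,
                         min_mean_q = 25, length_range = c(100L, 1000L),
                         fid_length = 10L, rid_length = 12L,
                         merge_near_rids = FALSE,
                         min_reads_for_consensus = 3L,
                         similarity_threshold = 0.8, linkage = "complete",
                         config = list()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  filt <- quality_length_filter(reads, min_mean_q, length_range)
  parsed <- parse_layout(filt$reads, layout, fid_length, rid_length)
  by_rep <- if ("replicate_id" %in% names(parsed$reads)) {
    split(parsed$reads, parsed$reads$replicate_id)
  } else list(`1` = parsed$reads)
  corrected_list <- lapply(names(by_rep), function(r) {
    grp <- group_by_rid(by_rep[[r]], merge_near_rids)
    rec <- correct_dataset(grp, min_reads_for_consensus)
    rec$replicate_id <- r
    rec
  })
  corrected <- do.call(rbind, lapply(corrected_list, as.data.frame))
  annotated <- annotate_rearrangements(corrected, db, layout, standards)
  bio <- annotated[!annotated$is_spikein, , drop = FALSE]
  clons <- NULL; incidence <- NULL; divers <- NULL
  if (nrow(bio) > 0 && any(bio$productive)) {
    clons <- cluster_clonotypes(bio, similarity_threshold, linkage)
    if (length(by_rep) > 1) {
      incidence <- clonotype_incidence(clons, bio)
      if (ncol(incidence) >= 2) {
        divers <- chao2(incidence_counts(incidence))
      }
    }
  }
  evaluation <- NULL
  if (!is.null(standards)) {
    spk <- annotated[annotated$is_spikein, , drop = FALSE]
    if (nrow(spk) > 0) {
      expected <- manifest %||% setNames(
        standards$standards$relative_concentration,
        standards$standards$standard_id)
      evaluation <- list(
        error_report = error_variant_report(spk, standards,
                                            sum(spk$read_count)),
        recovery = lapply(setNames(nm = c("reads", "rids", "corrected")),
                          function(m) frequency_recovery(spk, expected, m)))
    }
  }
  run_manifest <- list(
    package = "mafseq",
    version = as.character(utils::packageVersion("mafseq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    settings = list(min_mean_q = min_mean_q, length_range = length_range,
                    fid_length = fid_length, rid_length = rid_length,
                    merge_near_rids = merge_near_rids,
                    min_reads_for_consensus = min_reads_for_consensus,
                    similarity_threshold = similarity_threshold,
                    linkage = linkage),
    counts = list(input_reads = nrow(reads), filtered = filt$counts,
                  parsed = parsed$counts))
  out <- structure(list(parsed = parsed, corrected = corrected,
                        annotated = annotated, clonotypes = clons,
                        incidence = incidence, diversity = divers,
                        evaluation = evaluation, manifest = run_manifest),
                   class = "maf_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.maf_run <- function(x, ...) {
  cat("maf_run:", nrow(x$corrected), "corrected records,",
      nrow(x$annotated), "annotated;",
      if (is.null(x$clonotypes)) 0 else nrow(x$clonotypes$clonotypes),
      "clonotypes\n")
  invisible(x)
}

checksum_file <- function(path) unname(tools::md5sum(path))

#' Write the artifacts of a pipeline run
#' @param run a `maf_run`
#' @param out_dir output directory (created if needed)
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_parsed_tsv(run$parsed, file.path(out_dir, "parsed.tsv"))
  write.table(run$corrected, file.path(out_dir, "corrected.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_airr_tsv(run$annotated, file.path(out_dir, "rearrangements.tsv"))
  if (!is.null(run$clonotypes)) {
    write.table(run$clonotypes$clonotypes,
                file.path(out_dir, "clonotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$incidence)) {
    write_incidence_tsv(run$incidence, file.path(out_dir, "incidence.tsv"))
  }
  if (!is.null(run$diversity)) {
    jsonlite::write_json(
      list(estimator = run$diversity$estimator, point = run$diversity$point,
           se = run$diversity$se, ci = as.list(run$diversity$ci)),
      file.path(out_dir, "diversity.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$evaluation)) {
    ev <- run$evaluation
    jsonlite::write_json(
      list(median_cdr3_errors = ev$error_report$median_cdr3_errors,
           median_vdj_errors = ev$error_report$median_vdj_errors,
           r_squared = lapply(ev$recovery, `[[`, "r_squared"),
           mse_pp2 = lapply(ev$recovery, `[[`, "mse_pp2")),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- run$manifest
  artifacts <- list.files(out_dir, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "run_manifest.json"]
  manifest$artifact_checksums <- setNames(
    lapply(artifacts, checksum_file), basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

cli_message <- function(...) message("[mafseq] ", ...)

cli_fail <- function(msg, status) {
  cli_message("ERROR: ", msg)
  status
}

read_cli_config <- function(args) {
  i <- which(args == "--config")
  if (length(i) == 0) return(list())
  yaml::read_yaml(args[i[1] + 1])
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  args[i[1] + 1]
}

load_db_from_config <- function(cfg) {
  need <- c("germline_v", "germline_j")
  for (f in need) {
    if (is.null(cfg[[f]])) {
      stop_maf(paste0("config field missing: ", f), "mafseq_config_error")
    }
    if (!file.exists(cfg[[f]])) {
      stop_maf(paste0("config field '", f, "': file not found: ", cfg[[f]]),
               "mafseq_config_error")
    }
  }
  germline_database(
    load_germline_fasta(cfg$germline_v, "V"),
    load_germline_fasta(cfg$germline_j, "J"),
    if (!is.null(cfg$germline_c)) load_germline_fasta(cfg$germline_c, "C"))
}

#' Command-line entry point
#'
#' Subcommands: design-standards, validate-standards, simulate, preprocess,
#' correct, annotate, clonotype, diversity, evaluate, pipeline. Options are
#' read from `--config <yaml>` plus `--out <dir>` and `--seed <int>`
#' overrides. Exit codes: 0 ok, 1 runtime error, 2 configuration error.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments)
#' @return integer exit status, invisibly
#' @export
mafseq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cli_message("usage: mafseq <subcommand> --config config.yaml ",
                "[--out DIR] [--seed N]")
    return(invisible(2L))
  }
  sub <- args[1]
  status <- tryCatch({
    cfg <- read_cli_config(args)
    out_dir <- cli_opt(args, "--out", cfg$out_dir %||% "mafseq_out")
    seed <- as.integer(cli_opt(args, "--seed", cfg$seed %||% 1))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    switch(sub,
      "design-standards" = {
        db <- load_db_from_config(cfg)
        set <- design_standard_set(db, n_clones = cfg$n_clones %||% 85,
                                   seed = seed)
        write_standards_fasta(set, file.path(out_dir, "standards.fasta"))
        write_pool_manifest(set, file.path(out_dir, "manifest.tsv"))
        cli_message("designed ", nrow(set$standards), " standards")
      },
      "validate-standards" = {
        db <- load_db_from_config(cfg)
        set <- design_standard_set(db, n_clones = cfg$n_clones %||% 85,
                                   seed = seed)
        rep_ <- validate_standard_set(set, db)
        print(rep_)
        if (!rep_$pass) stop_maf("validation failed", "mafseq_runtime_error")
      },
      "simulate" = {
        db <- load_db_from_config(cfg)
        layout <- default_layout(db)
        set <- design_standard_set(db, n_clones = cfg$n_clones %||% 85,
                                   seed = seed)
        params <- simulator_params(
          n_transcripts = cfg$n_transcripts %||% 1000,
          seq_error_rate = cfg$seq_error_rate %||% 0,
          pcr_error_rate = cfg$pcr_error_rate %||% 0, seed = seed)
        mols <- transcribe_and_tag(params, spikeins = set)
        amplify_and_sequence(mols, params,
                             out_prefix = file.path(out_dir, "sim"))
        write_standards_fasta(set, file.path(out_dir, "standards.fasta"))
        write_pool_manifest(set, file.path(out_dir, "manifest.tsv"))
        cli_message("simulated reads under ", out_dir)
      },
      "preprocess" = {
        db <- load_db_from_config(cfg)
        layout <- default_layout(db)
        reads <- read_fastq(cfg$fastq)
        filt <- quality_length_filter(reads, cfg$min_mean_q %||% 25,
                                      cfg$length_range %||% c(100, 1000))
        parsed <- parse_layout(filt$reads, layout)
        write_parsed_tsv(parsed, file.path(out_dir, "parsed.tsv"))
        jsonlite::write_json(as.list(c(filt$counts, parsed$counts)),
                             file.path(out_dir, "preprocess_stats.json"),
                             auto_unbox = TRUE)
      },
      "correct" = {
        parsed <- read_parsed_tsv(cfg$parsed_tsv)
        grp <- group_by_rid(parsed, isTRUE(cfg$merge_near_rids))
        rec <- correct_dataset(grp, cfg$min_reads_for_consensus %||% 3)
        write.table(rec, file.path(out_dir, "corrected.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      },
      "annotate" = {
        db <- load_db_from_config(cfg)
        layout <- default_layout(db)
        rec <- read.delim(cfg$corrected_tsv, stringsAsFactors = FALSE)
        ann <- annotate_rearrangements(rec, db, layout)
        write_airr_tsv(ann, file.path(out_dir, "rearrangements.tsv"))
      },
      "clonotype" = {
        ann <- read_airr_tsv(cfg$rearrangements_tsv)
        clons <- cluster_clonotypes(ann, cfg$similarity_threshold %||% 0.8,
                                    cfg$linkage %||% "complete")
        write.table(clons$clonotypes, file.path(out_dir, "clonotypes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "diversity" = {
        mat <- read_incidence_tsv(cfg$incidence_tsv)
        est <- chao2(incidence_counts(mat))
        jsonlite::write_json(
          list(estimator = est$estimator, point = est$point, se = est$se,
               ci = as.list(est$ci)),
          file.path(out_dir, "diversity.json"), auto_unbox = TRUE, digits = NA)
      },
      "evaluate" = {
        db <- load_db_from_config(cfg)
        layout <- default_layout(db)
        set <- design_standard_set(db, n_clones = cfg$n_clones %||% 85,
                                   seed = seed)
        ann <- read_airr_tsv(cfg$rearrangements_tsv)
        spk <- ann[ann$is_spikein, , drop = FALSE]
        expected <- read_pool_manifest(cfg$manifest)
        rep_ <- error_variant_report(spk, set, sum(spk$read_count))
        rec <- frequency_recovery(spk, expected, "corrected")
        jsonlite::write_json(
          list(median_cdr3_errors = rep_$median_cdr3_errors,
               median_vdj_errors = rep_$median_vdj_errors,
               r_squared = rec$r_squared, mse_pp2 = rec$mse_pp2),
          file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
          digits = NA)
      },
      "pipeline" = {
        db <- load_db_from_config(cfg)
        layout <- default_layout(db)
        standards <- NULL
        manifest <- NULL
        if (!is.null(cfg$manifest)) manifest <- read_pool_manifest(cfg$manifest)
        if (isTRUE(cfg$with_standards)) {
          standards <- design_standard_set(db, n_clones = cfg$n_clones %||% 85,
                                           seed = cfg$standards_seed %||% 1)
        }
        run_pipeline(cfg$fastq, db, layout, standards, manifest,
                     out_dir = out_dir,
                     min_mean_q = cfg$min_mean_q %||% 25,
                     length_range = cfg$length_range %||% c(100, 1000),
                     merge_near_rids = isTRUE(cfg$merge_near_rids),
                     config = cfg)
        cli_message("pipeline artifacts under ", out_dir)
      },
      stop_maf(paste0("unknown subcommand: ", sub), "mafseq_config_error"))
    0L
  },
  mafseq_config_error = function(e) cli_fail(conditionMessage(e), 2L),
  error = function(e) cli_fail(conditionMessage(e), 1L))
  invisible(status)
}
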