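#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML path or a named list; fills defaults, rejects unknown
#' keys, and type-checks every field. The normalised configuration
#' re-validates to itself (fixed point).
#'
#' @param config YAML file path or named list. Recognised keys: `seed`,
#'   `scenario` (overrides of [default_scenario()] fields), `binning`
#'   (overrides of [binning_params()] arguments), `refine` (overrides of
#'   [refine_thresholds()] arguments), `stages` (logical toggles `simulate`,
#'   `features`, `bin`, `refine`, `qc`, `oligo`, `nj`), `nj_bootstrap`
#'   (replicates for the 16S tree).
#' @return Named list of class `rm_config` with every field filled.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  known <- c("seed", "scenario", "binning", "refine", "stages", "nj_bootstrap")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0L) abort(paste0("Unknown config key: ", bad[1L]))

  out <- list(
    seed = config$seed %||% 1L,
    scenario = do.call(default_scenario, as.list(config$scenario)),
    binning = do.call(binning_params, as.list(config$binning)),
    refine = do.call(refine_thresholds, as.list(config$refine)),
    stages = list(simulate = TRUE, features = TRUE, bin = TRUE,
                  refine = TRUE, qc = TRUE, oligo = TRUE, nj = TRUE),
    nj_bootstrap = config$nj_bootstrap %||% 100L
  )
  if (!is.numeric(out$seed) || length(out$seed) != 1L) {
    abort("`seed` must be a single integer.")
  }
  st <- config$stages
  if (!is.null(st)) {
    bad <- setdiff(names(st), names(out$stages))
    if (length(bad) > 0L) abort(paste0("Unknown stage toggle: ", bad[1L]))
    for (nm in names(st)) {
      if (!is.logical(st[[nm]])) abort(paste0("Stage toggle not logical: ", nm))
      out$stages[[nm]] <- st[[nm]]
    }
  }
  if (out$nj_bootstrap < 1) abort("`nj_bootstrap` must be >= 1.")
  structure(out, class = "rm_config")
}

#' Score recovered bins against the synthetic truth
#'
#' Length-weighted precision and recall of every bin against every genome;
#' the target bin is the bin with the highest recall of the target genome.
#'
#' @param bins `rm_bins` assignment tibble.
#' @param truth Contig provenance tibble (`contig_id`, `genome_id`).
#' @param features `rm_features` tibble (contig lengths).
#' @param target_id Target genome id.
#' @return List of class `rm_scorecard`: `per_bin` tibble (`bin_id`,
#'   `genome_id`, `precision`, `recall`), `target_bin`, `target_precision`,
#'   `target_recall`.
#' @export
score_recovery <- function(bins, truth, features, target_id) {
  df <- left_join(as_tibble(bins),
                  truth[, c("contig_id", "genome_id")], by = "contig_id")
  df <- left_join(df, tibble(contig_id = features$contig_id,
                             length = features$length), by = "contig_id")
  df <- filter(df, .data$bin_id != "unbinned")
  genome_bp <- summarise(group_by(left_join(
    truth[, c("contig_id", "genome_id")],
    tibble(contig_id = features$contig_id, length = features$length),
    by = "contig_id"), .data$genome_id),
    genome_bp = sum(.data$length), .groups = "drop")
  per <- summarise(group_by(df, .data$bin_id, .data$genome_id),
                   bp = sum(.data$length), .groups = "drop_last")
  per <- mutate(per, bin_bp = sum(.data$bp))
  per <- ungroup(per)
  per <- left_join(per, genome_bp, by = "genome_id")
  per <- mutate(per, precision = .data$bp / .data$bin_bp,
                recall = .data$bp / .data$genome_bp)
  tgt <- filter(per, .data$genome_id == target_id)
  if (nrow(tgt) == 0L) {
    out <- list(per_bin = per[, c("bin_id", "genome_id", "precision",
                                  "recall")],
                target_bin = NA_character_, target_precision = 0,
                target_recall = 0)
  } else {
    best <- tgt[order(-tgt$recall, tgt$bin_id)[1L], ]
    out <- list(per_bin = per[, c("bin_id", "genome_id", "precision",
                                  "recall")],
                target_bin = best$bin_id,
                target_precision = best$precision,
                target_recall = best$recall)
  }
  structure(out, class = "rm_scorecard")
}

#' @export
print.rm_scorecard <- function(x, ...) {
  cat("<rm_scorecard> target bin ", x$target_bin,
      sprintf(": precision %.3f, recall %.3f (by length)\n",
              x$target_precision, x$target_recall), sep = "")
  invisible(x)
}

#' @export
tidy.rm_scorecard <- function(x, ...) x$per_bin

#' @export
glance.rm_scorecard <- function(x, ...) {
  tibble(target_bin = x$target_bin,
         target_precision = x$target_precision,
         target_recall = x$target_recall)
}

#' Run the full recovery pipeline on a synthetic scenario
#'
#' Chains simulate -> features -> bin -> refine -> qc (plus optional 16S
#' oligo design and NJ tree stages), writes every stage artifact plus a
#' checksummed manifest to `outdir`, and scores the recovered bins against
#' the synthetic truth. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config [validate_config()] input (list or YAML path).
#' @param outdir Output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return List of class `rm_run`: `community`, `features`, `bins`,
#'   `refined`, `report`, `qc`, `scorecard`, `oligos`, `tree`, `manifest`.
#' @export
run_all <- function(config = list(), outdir = NULL) {
  cfg <- validate_config(config)
  st <- cfg$stages
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  artifacts <- character(0)
  save_file <- function(writer, file) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, file)
    writer(path)
    artifacts <<- c(artifacts, path)
    invisible(path)
  }
  stage <- function(name, code) {
    inform(paste0("[", name, "] running"))
    tryCatch(code, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (!st$simulate) abort("The simulate stage cannot be disabled: it provides every downstream input.")
  community <- stage("simulate", simulate_community(cfg$scenario, cfg$seed))
  save_file(function(p) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(community$contigs), p, width = 80)
  }, "contigs.fasta")
  save_file(function(p) readr::write_tsv(community$coverage, p),
            "coverage.tsv")
  save_file(function(p) readr::write_tsv(community$wells, p), "wells.tsv")
  save_file(function(p) readr::write_tsv(community$markers, p), "markers.tsv")
  save_file(function(p) jsonlite::write_json(
    list(contig_map = community$truth$contig_map,
         abundances = community$truth$abundances,
         insert = community$truth$insert),
    p, auto_unbox = TRUE, digits = NA), "truth.json")
  save_file(function(p) Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(community$rrna$alignment), p, width = 80),
    "16s_aln.fasta")

  result <- list(community = community)

  if (st$features) {
    features <- stage("features",
                      build_features(community$contigs, community$coverage))
    save_file(function(p) write_features(features, p), "features.tsv")
    result$features <- features
  }
  if (st$features && st$bin) {
    bins <- stage("bin", bin_contigs(features, cfg$binning))
    save_file(function(p) readr::write_tsv(as_tibble(bins), p), "bins.tsv")
    result$bins <- bins
  }
  if (st$features && st$bin && st$refine) {
    rf <- stage("refine", refine_bins(bins, features,
                                      wells = community$wells,
                                      thresholds = cfg$refine))
    save_file(function(p) readr::write_tsv(as_tibble(rf$bins), p),
              "refined_bins.tsv")
    save_file(function(p) jsonlite::write_json(rf$report, p,
                                               auto_unbox = TRUE, digits = NA),
              "refinement_report.json")
    result$refined <- rf$bins
    result$report <- rf$report
    final_bins <- rf$bins
  } else if (st$features && st$bin) {
    final_bins <- bins
  }
  if (st$features && st$bin && st$qc) {
    marker_set <- sort(unique(community$markers$marker_id))
    sc <- stage("score", score_recovery(final_bins,
                                        community$truth$contig_map,
                                        features, community$target_id))
    result$scorecard <- sc
    if (!is.na(sc$target_bin)) {
      tb <- final_bins$contig_id[final_bins$bin_id == sc$target_bin]
      qc <- stage("qc", bin_qc(tb, features, community$markers, marker_set))
      result$qc <- qc
      save_file(function(p) readr::write_tsv(qc_report(qc), p),
                "qc_report.tsv")
      save_file(function(p) jsonlite::write_json(as.list(as_tibble(qc)), p,
                                                 auto_unbox = TRUE,
                                                 digits = NA),
                "qc_report.json")
    }
    save_file(function(p) jsonlite::write_json(
      list(per_bin = sc$per_bin, target_bin = sc$target_bin,
           target_precision = sc$target_precision,
           target_recall = sc$target_recall),
      p, auto_unbox = TRUE, digits = NA), "scorecard.json")
  }
  if (st$oligo) {
    aln <- community$rrna$alignment
    tid <- community$rrna$target_id
    oligos <- stage("oligo", design_oligos(
      aln[tid], aln[setdiff(names(aln), tid)], k = 20, min_mismatch = 2))
    save_file(function(p) readr::write_tsv(as_tibble(oligos), p),
              "oligos.tsv")
    result$oligos <- oligos
  }
  if (st$nj) {
    tree <- stage("nj", bootstrap_support(community$rrna$alignment,
                                          n_replicates = cfg$nj_bootstrap,
                                          seed = cfg$seed))
    save_file(function(p) write_newick(tree, p), "16s_nj.nwk")
    result$tree <- tree
  }

  if (!is.null(outdir)) {
    manifest <- tibble(
      file = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stage = "run_all",
      seed = cfg$seed
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  structure(result, class = "rm_run")
}

#' @export
print.rm_run <- function(x, ...) {
  cat("<rm_run>\n")
  if (!is.null(x$scorecard)) print(x$scorecard)
  if (!is.null(x$qc)) {
    cat(sprintf("  target bin: %.2f Mb, %d contigs, N50 %d\n",
                x$qc$size_mb, x$qc$n_contigs, x$qc$n50))
  }
  invisible(x)
}

#' @export
glance.rm_run <- function(x, ...) {
  sc <- x$scorecard
  out <- tibble(target_bin = sc$target_bin,
                target_precision = sc$target_precision,
                target_recall = sc$target_recall)
  if (!is.null(x$qc)) {
    out$completeness <- x$qc$completeness
    out$contamination <- x$qc$contamination
    out$abundance_pct_mean <- x$qc$abundance_pct_mean
  }
  out
}
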