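#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L together cover at
#' least half the total assembly.
#'
#' @param lengths Positive contig lengths (bp).
#' @return N50 in bp.
#' @export
#' @examples
#' n50(c(10, 8, 5, 3)) # 8
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("`lengths` must be non-empty.")
  if (any(lengths <= 0)) abort("`lengths` must all be > 0.")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly-style summary of a bin
#'
#' Size (Mb), contig count, N50, length-weighted GC (%), and per-sample
#' median contig coverage.
#'
#' @param bin_contig_ids Contigs of the bin.
#' @param features `rm_features` tibble containing them.
#' @return One-row tibble: `size_mb`, `n_contigs`, `n50`, `gc_percent`, and
#'   one `median_cov_<sample>` column per sample.
#' @export
bin_summary <- function(bin_contig_ids, features) {
  idx <- match(bin_contig_ids, features$contig_id)
  if (anyNA(idx)) {
    abort(paste0("Contig missing from feature table: ",
                 bin_contig_ids[is.na(idx)][1L]))
  }
  sub <- features[idx, ]
  covm <- do.call(rbind, sub$coverage)
  med <- apply(covm, 2, median)
  out <- tibble(
    size_mb = sum(sub$length) / 1e6,
    n_contigs = nrow(sub),
    n50 = n50(sub$length),
    gc_percent = 100 * sum(sub$gc * sub$length) / sum(sub$length)
  )
  for (s in colnames(covm)) out[[paste0("median_cov_", s)]] <- med[[s]]
  out
}

#' Single-copy-marker completeness and contamination
#'
#' Against a universal single-copy marker set: completeness is the
#' percentage of markers with at least one copy on the bin's contigs;
#' contamination is the percentage of surplus copies,
#' `100 * sum(max(copies_m - 1, 0)) / |marker set|`. A simplified
#' single-copy-marker analog of lineage-workflow bin QC — marker hits are an
#' input table from any scanner, no HMM search is run here.
#'
#' @param bin_contig_ids Contigs of the bin.
#' @param marker_hits Tibble `contig`, `marker_id`, `copies`.
#' @param marker_set Character vector of expected marker ids.
#' @return List: `completeness`, `contamination` (both %).
#' @export
completeness_contamination <- function(bin_contig_ids, marker_hits,
                                       marker_set) {
  if (length(marker_set) == 0L) abort("`marker_set` must be non-empty.")
  unknown <- setdiff(marker_hits$marker_id, marker_set)
  if (length(unknown) > 0L) {
    abort(paste0("Marker hit references unknown marker: ", unknown[1L]))
  }
  hits <- marker_hits[marker_hits$contig %in% bin_contig_ids, , drop = FALSE]
  copies <- tapply(hits$copies, hits$marker_id, sum)
  present <- sum(names(copies) %in% marker_set & copies >= 1)
  surplus <- sum(pmax(copies - 1, 0))
  list(completeness = 100 * present / length(marker_set),
       contamination = 100 * surplus / length(marker_set))
}

#' Relative abundance of a bin in the community
#'
#' Per sample, 100 times the bin's share of total length-times-coverage mass
#' (coverage mass approximates read share). Also reports the mean over
#' samples.
#'
#' @param bin_contig_ids Contigs of the bin.
#' @param features `rm_features` tibble for the whole community.
#' @return List: `per_sample` (named %), `mean` (%).
#' @export
relative_abundance <- function(bin_contig_ids, features) {
  covm <- coverage_matrix(features)
  mass <- covm * features$length
  total <- colSums(mass)
  if (all(total == 0)) abort("Community has zero total coverage mass.")
  in_bin <- features$contig_id %in% bin_contig_ids
  pct <- 100 * colSums(mass[in_bin, , drop = FALSE]) / total
  names(pct) <- attr(features, "samples")
  list(per_sample = pct, mean = mean(pct))
}

#' Full QC report of a bin
#'
#' Combines [bin_summary()], [completeness_contamination()] and
#' [relative_abundance()] into one record.
#'
#' @param bin_contig_ids Contigs of the bin.
#' @param features `rm_features` tibble.
#' @param marker_hits,marker_set Optional marker inputs for
#'   completeness/contamination.
#' @return One-row tibble of class `rm_qc`.
#' @export
bin_qc <- function(bin_contig_ids, features, marker_hits = NULL,
                   marker_set = NULL) {
  out <- bin_summary(bin_contig_ids, features)
  if (!is.null(marker_hits) && !is.null(marker_set)) {
    cc <- completeness_contamination(bin_contig_ids, marker_hits, marker_set)
    out$completeness <- cc$completeness
    out$contamination <- cc$contamination
  }
  ra <- relative_abundance(bin_contig_ids, features)
  for (s in names(ra$per_sample)) {
    out[[paste0("abundance_pct_", s)]] <- ra$per_sample[[s]]
  }
  out$abundance_pct_mean <- ra$mean
  structure(out, class = c("rm_qc", class(out)))
}

#' Two-column report with conventional summary-table row names
#'
#' @param qc An `rm_qc` row from [bin_qc()].
#' @return Tibble `statistic`, `value` using the field's customary row names
#'   ("Bin size (Mb)", "Number of contigs", "N50 value", "GC content (%)",
#'   "Completeness (%)", "Contamination (%)", "Median coverage in <sample>").
#' @export
qc_report <- function(qc) {
  rows <- list(
    "Bin size (Mb)" = round(qc$size_mb, 2),
    "Number of contigs" = qc$n_contigs,
    "N50 value" = qc$n50,
    "GC content (%)" = round(qc$gc_percent, 1)
  )
  if (!is.null(qc$completeness)) {
    rows[["Completeness (%)"]] <- round(qc$completeness, 2)
    rows[["Contamination (%)"]] <- round(qc$contamination, 2)
  }
  for (nm in grep("^median_cov_", names(qc), value = TRUE)) {
    rows[[paste0("Median coverage in ", sub("^median_cov_", "", nm))]] <-
      round(qc[[nm]], 1)
  }
  for (nm in grep("^abundance_pct_", names(qc), value = TRUE)) {
    rows[[paste0("Relative abundance (%) in ",
                 sub("^abundance_pct_", "", nm))]] <- round(qc[[nm]], 2)
  }
  tibble(statistic = names(rows), value = unlist(rows, use.names = FALSE))
}

#' @export
tidy.rm_qc <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}
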