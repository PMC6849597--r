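#' Refinement thresholds
#'
#' @param tau Log2-fold coverage-ratio tolerance per sample.
#' @param s_max Number of samples allowed to exceed `tau` before a contig is
#'   called coverage-incompatible.
#' @param presence_min Well coverage (fold) at which a contig counts as
#'   present in a well; presence/absence is used because MDA bias makes well
#'   depth quantitative comparisons unreliable.
#' @param e_min Minimum well-enrichment score (`-log10 p`) for mini-metagenome
#'   co-occurrence evidence; the default 2.0 corresponds to p <= 0.01.
#' @return Named list.
#' @export
refine_thresholds <- function(tau = 1.0, s_max = 0L, presence_min = 1.0,
                              e_min = 2.0) {
  list(tau = tau, s_max = as.integer(s_max), presence_min = presence_min,
       e_min = e_min)
}

#' Coverage-profile compatibility of a contig with a bin
#'
#' Per sample, `r = log2((contig_cov + 0.1) / (bin median cov + 0.1))`; the
#' contig is incompatible when `|r| > tau` in more than `s_max` samples.
#' Bins with fewer than 3 contigs cannot define a stable median profile and
#' are treated as trivially compatible, with a warning.
#'
#' @param contig_id Contig to test.
#' @param bin_contig_ids Contigs defining the bin's coverage profile.
#' @param features `rm_features` tibble containing both.
#' @param tau Log2-fold tolerance (default 1.0).
#' @param s_max Allowed number of deviant samples (default 0).
#' @return List: `compatible` (flag), `deviation` (named per-sample log2
#'   ratios).
#' @export
coverage_compatibility <- function(contig_id, bin_contig_ids, features,
                                   tau = 1.0, s_max = 0L) {
  i <- match(contig_id, features$contig_id)
  if (is.na(i)) abort(paste0("Contig not in feature table: ", contig_id))
  covm <- coverage_matrix(features)
  rownames(covm) <- features$contig_id
  cc <- covm[i, ]
  if (length(bin_contig_ids) < 3L) {
    warn("Bin has fewer than 3 contigs; coverage compatibility is trivial.")
    return(list(compatible = TRUE,
                deviation = setNames(rep(0, length(cc)), names(cc))))
  }
  med <- apply(covm[bin_contig_ids, , drop = FALSE], 2, median)
  r <- log2((cc + 0.1) / (med + 0.1))
  list(compatible = sum(abs(r) > tau) <= s_max, deviation = r)
}

#' Mini-metagenome co-occurrence enrichment of a contig
#'
#' A contig is "present" in a well when its coverage is at least
#' `presence_min`. With k = presence calls among the m target-enriched wells
#' and background rate p0 = overall fraction of presence calls (all contigs,
#' enriched wells), the score is `-log10 P(X >= k)` for X ~ Binomial(m, p0):
#' how surprising the contig's co-occurrence with the target-sorted wells is.
#'
#' @param contig_id Contig to score.
#' @param wells Well coverage tibble from [simulate_wells()] (or the same
#'   shape with an `enriched` attribute, or all wells treated as enriched).
#' @param presence_min Presence threshold (fold).
#' @return Non-negative score (`-log10` of the binomial tail probability).
#' @export
well_enrichment <- function(contig_id, wells, presence_min = 1.0) {
  enriched <- attr(wells, "enriched")
  well_cols <- setdiff(names(wells), "contig")
  if (is.null(enriched)) enriched <- setNames(rep(TRUE, length(well_cols)),
                                              well_cols)
  ecols <- well_cols[enriched[well_cols]]
  m <- length(ecols)
  if (m == 0L) abort("No target-enriched wells.")
  pres <- as.matrix(wells[, ecols, drop = FALSE]) >= presence_min
  p0 <- mean(pres)
  i <- match(contig_id, wells$contig)
  if (is.na(i)) abort(paste0("Contig not in well table: ", contig_id))
  k <- sum(pres[i, ])
  p <- pbinom(k - 1L, size = m, prob = min(p0, 1), lower.tail = FALSE)
  max(0, -log10(p))
}

#' Majority taxon of a bin and its outliers
#'
#' The bin's label at `rank` is the label with the largest summed contig
#' length; labelled contigs disagreeing with it are outliers. Unlabelled
#' contigs (absent from the table or `NA`) are never outliers; a bin with no
#' labelled contig gets majority `"unclassified"`.
#'
#' @param bin_contig_ids Contigs of the bin.
#' @param taxon_table Tibble with `contig_id` and one column per rank.
#' @param rank Column of `taxon_table` to use.
#' @param features `rm_features` tibble (contig lengths for the weighting).
#' @return List: `majority` (label), `outliers` (contig ids).
#' @export
taxon_consistency <- function(bin_contig_ids, taxon_table, rank, features) {
  if (length(bin_contig_ids) == 0L) abort("Empty bin.")
  if (!rank %in% names(taxon_table)) {
    abort(paste0("Rank column not in taxon table: ", rank))
  }
  lab <- taxon_table[[rank]][match(bin_contig_ids, taxon_table$contig_id)]
  len <- features$length[match(bin_contig_ids, features$contig_id)]
  labelled <- !is.na(lab)
  if (!any(labelled)) {
    return(list(majority = "unclassified", outliers = character(0)))
  }
  mass <- tapply(len[labelled], lab[labelled], sum)
  majority <- names(mass)[order(-mass, names(mass))][1L]
  outliers <- bin_contig_ids[labelled & lab != majority]
  list(majority = majority, outliers = outliers)
}

#' Refine one bin with coverage, taxonomy and well co-occurrence evidence
#'
#' Iterates to a fixed point: contigs failing [coverage_compatibility()]
#' against the bin's median profile are removed; taxon outliers
#' ([taxon_consistency()]) are removed unless rescued by mini-metagenome
#' co-occurrence ([well_enrichment()] at least `e_min`). Iterating makes
#' refinement idempotent.
#'
#' @param bin_contig_ids Contigs of the candidate bin.
#' @param features `rm_features` tibble.
#' @param wells Optional well coverage tibble.
#' @param taxon_table Optional taxon label tibble (see
#'   [taxon_consistency()]).
#' @param rank Rank column used when `taxon_table` is given.
#' @param thresholds [refine_thresholds()].
#' @return List: `contig_ids` (refined bin), `report` tibble
#'   (`contig_id`, `action`, `reason`, `evidence`).
#' @export
refine_bin <- function(bin_contig_ids, features, wells = NULL,
                       taxon_table = NULL, rank = NULL,
                       thresholds = refine_thresholds()) {
  current <- sort(bin_contig_ids)
  report <- tibble(contig_id = character(), action = character(),
                   reason = character(), evidence = numeric())
  repeat {
    removed <- character(0)
    if (length(current) >= 3L) {
      for (cid in current) {
        cc <- coverage_compatibility(cid, current, features,
                                     thresholds$tau, thresholds$s_max)
        if (!cc$compatible) {
          removed <- c(removed, cid)
          report <- bind_rows(report, tibble(
            contig_id = cid, action = "removed",
            reason = "coverage_incompatible",
            evidence = max(abs(cc$deviation))))
        }
      }
    }
    remaining <- setdiff(current, removed)
    if (!is.null(taxon_table) && !is.null(rank) && length(remaining) > 0L) {
      tc <- taxon_consistency(remaining, taxon_table, rank, features)
      for (cid in tc$outliers) {
        score <- if (!is.null(wells)) {
          well_enrichment(cid, wells, thresholds$presence_min)
        } else 0
        if (score < thresholds$e_min) {
          removed <- c(removed, cid)
          report <- bind_rows(report, tibble(
            contig_id = cid, action = "removed", reason = "taxon_outlier",
            evidence = score))
        }
      }
    }
    if (length(removed) == 0L) break
    current <- setdiff(current, removed)
    if (length(current) == 0L) break
  }
  list(contig_ids = current, report = report)
}

#' Associate an unbinned contig to its best bin
#'
#' Candidate bins are those the contig is coverage-compatible with; when a
#' candidate bin is itself well-enriched (median member enrichment score at
#' least `e_min`), the contig must also reach `e_min` to qualify. Among
#' candidates, the bin with the smallest coverage deviation norm wins; ties
#' break by bin id. The route by which, e.g., a short rRNA-bearing contig
#' joins the target bin.
#'
#' @param contig_id Unbinned contig.
#' @param bins `rm_bins` assignment tibble.
#' @param features `rm_features` tibble.
#' @param wells Optional well coverage tibble.
#' @param thresholds [refine_thresholds()].
#' @return List: `bin_id` (or `NA` if no candidate), `deviation` (norm), or
#'   `NA` entries when unassigned.
#' @export
associate_unbinned <- function(contig_id, bins, features, wells = NULL,
                               thresholds = refine_thresholds()) {
  bin_ids <- sort(setdiff(unique(bins$bin_id), "unbinned"))
  cand <- character(0); devs <- numeric(0)
  for (b in bin_ids) {
    members <- bins$contig_id[bins$bin_id == b]
    cc <- suppressWarnings(
      coverage_compatibility(contig_id, members, features,
                             thresholds$tau, thresholds$s_max))
    if (!cc$compatible) next
    if (!is.null(wells)) {
      member_scores <- vapply(members, well_enrichment, numeric(1),
                              wells = wells,
                              presence_min = thresholds$presence_min)
      if (median(member_scores) >= thresholds$e_min) {
        score <- well_enrichment(contig_id, wells, thresholds$presence_min)
        if (score < thresholds$e_min) next
      }
    }
    cand <- c(cand, b)
    devs <- c(devs, sqrt(sum(cc$deviation^2)))
  }
  if (length(cand) == 0L) return(list(bin_id = NA_character_,
                                      deviation = NA_real_))
  ord <- order(devs, cand)
  list(bin_id = cand[ord[1L]], deviation = devs[ord[1L]])
}

#' Refine every bin and associate unbinned contigs
#'
#' Applies [refine_bin()] to each bin, then [associate_unbinned()] to every
#' contig left unbinned (including those released by refinement).
#'
#' @param bins `rm_bins` tibble from [bin_contigs()].
#' @param features `rm_features` tibble.
#' @param wells Optional well coverage tibble.
#' @param taxon_table,rank Optional taxon labels (see [taxon_consistency()]).
#' @param thresholds [refine_thresholds()].
#' @return List: `bins` (refined `rm_bins` tibble), `report` (actions with
#'   evidence, including associations).
#' @export
refine_bins <- function(bins, features, wells = NULL, taxon_table = NULL,
                        rank = NULL, thresholds = refine_thresholds()) {
  bin_ids <- sort(setdiff(unique(bins$bin_id), "unbinned"))
  reports <- list(); assignments <- list()
  released <- character(0)
  for (b in bin_ids) {
    members <- bins$contig_id[bins$bin_id == b]
    rf <- refine_bin(members, features, wells, taxon_table, rank, thresholds)
    released <- c(released, setdiff(members, rf$contig_ids))
    if (nrow(rf$report) > 0L) {
      reports[[b]] <- mutate(rf$report, bin_id = b)
    }
    assignments[[b]] <- tibble(contig_id = rf$contig_ids, bin_id = b,
                               provenance = "refined")
  }
  assigned <- bind_rows(assignments)
  unbinned <- union(bins$contig_id[bins$bin_id == "unbinned"], released)
  extra <- list()
  for (cid in sort(unbinned)) {
    hit <- associate_unbinned(cid, assigned, features, wells, thresholds)
    if (!is.na(hit$bin_id)) {
      extra[[cid]] <- tibble(contig_id = cid, bin_id = hit$bin_id,
                             provenance = "associated")
      reports[[paste0("assoc_", cid)]] <- tibble(
        contig_id = cid, action = "added", reason = "associated",
        evidence = hit$deviation, bin_id = hit$bin_id)
    } else {
      extra[[cid]] <- tibble(contig_id = cid, bin_id = "unbinned",
                             provenance = "unbinned")
    }
  }
  out <- arrange(bind_rows(assigned, bind_rows(extra)), .data$contig_id)
  list(bins = structure(out, class = c("rm_bins", class(out))),
       report = bind_rows(reports))
}
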