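#' Binning parameters
#'
#' Free parameters of the abundance-prepartitioned composition + differential
#' coverage binner.
#'
#' @param n_strata Number of abundance strata (1-20).
#' @param stratum_overlap Fractional widening of each stratum band on each
#'   side, so boundary contigs appear in both neighbouring strata.
#' @param tnf_weight Weight `w` in \[0, 1\] of the compositional term of
#'   [contig_distance()]; `1 - w` weights the differential-coverage term.
#' @param linkage_cutoff Average-linkage cut height `t`; `NULL` picks it from
#'   the knee of the linkage-height curve.
#' @param min_bin_size Minimum summed contig length (bp) for a cluster to be
#'   reported as a bin; smaller clusters are emitted as unbinned.
#' @return Named list of class `rm_binning_params`.
#' @export
binning_params <- function(n_strata = 3, stratum_overlap = 0.1,
                           tnf_weight = 0.5, linkage_cutoff = NULL,
                           min_bin_size = 2e5) {
  if (n_strata < 1 || n_strata > 20) abort("`n_strata` must be in [1, 20].")
  if (tnf_weight < 0 || tnf_weight > 1) abort("`tnf_weight` must be in [0, 1].")
  if (!is.null(linkage_cutoff) && linkage_cutoff <= 0) {
    abort("`linkage_cutoff` must be > 0.")
  }
  structure(list(n_strata = as.integer(n_strata),
                 stratum_overlap = stratum_overlap,
                 tnf_weight = tnf_weight, linkage_cutoff = linkage_cutoff,
                 min_bin_size = min_bin_size),
            class = "rm_binning_params")
}

#' Pre-partition contigs into abundance strata
#'
#' Strata are quantile bands of `log1p(mean coverage)`; each band is widened
#' by `stratum_overlap` times its width on both sides, so contigs near a
#' boundary are clustered in both neighbouring strata (duplicates are
#' resolved by [merge_strata()]).
#'
#' @param features An `rm_features` tibble.
#' @param n_strata Number of bands (>= 1).
#' @param stratum_overlap Fractional band widening per side.
#' @return Tibble `contig_id`, `stratum` (integer); contigs in overlap zones
#'   appear on several rows.
#' @export
prepartition <- function(features, n_strata = 3, stratum_overlap = 0.1) {
  if (n_strata < 1) abort("`n_strata` must be >= 1.")
  x <- log1p(vapply(features$coverage, mean, numeric(1)))
  if (all(x == 0)) {
    warn("All contigs have zero coverage; using a single stratum.")
    return(tibble(contig_id = features$contig_id, stratum = 1L))
  }
  if (n_strata == 1L) {
    return(tibble(contig_id = features$contig_id, stratum = 1L))
  }
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_strata + 1)))
  if (length(br) < 3L) {
    return(tibble(contig_id = features$contig_id, stratum = 1L))
  }
  k <- length(br) - 1L
  out <- lapply(seq_len(k), function(i) {
    w <- (br[i + 1] - br[i]) * stratum_overlap
    lo <- br[i] - w
    hi <- br[i + 1] + w
    inside <- if (i == 1L) x <= hi else if (i == k) x >= lo
      else x >= lo & x <= hi
    tibble(contig_id = features$contig_id[inside], stratum = i)
  })
  distinct(arrange(bind_rows(out), .data$stratum, .data$contig_id))
}

# clr over the 136-tetramer simplex. Frequencies are first Laplace-smoothed
# at the count level — (count + 1) / (windows + 136), counts reconstructed
# from contig length — so zero-count tetramers on short contigs do not
# produce unbounded log-ratio spikes.
clr_tnf <- function(tnfm, lengths) {
  windows <- pmax(lengths - 3, 1)
  counts <- tnfm * windows
  sm <- (counts + 1) / (windows + ncol(tnfm))
  lx <- log(sm)
  lx - rowMeans(lx)
}

#' Composition + differential-coverage distance between two contigs
#'
#' `d = w * ||clr(tnf_a) - clr(tnf_b)||_2 / sqrt(136) +
#' (1 - w) * ||log1p(cov_a) - log1p(cov_b)||_2 / sqrt(S)` with S samples.
#' A weighted sum of two metrics, hence itself a metric.
#'
#' @param a,b Single rows of an `rm_features` tibble (or lists with `tnf`
#'   and `coverage` elements).
#' @param w Compositional weight in \[0, 1\].
#' @return Non-negative scalar.
#' @export
contig_distance <- function(a, b, w = 0.5) {
  ta <- if (is.data.frame(a)) a$tnf[[1]] else a$tnf
  tb <- if (is.data.frame(b)) b$tnf[[1]] else b$tnf
  ca <- if (is.data.frame(a)) a$coverage[[1]] else a$coverage
  cb <- if (is.data.frame(b)) b$coverage[[1]] else b$coverage
  la <- if (is.data.frame(a)) a$length[[1]] else a$length
  lb <- if (is.data.frame(b)) b$length[[1]] else b$length
  if (length(ca) != length(cb)) abort("Coverage dimensions differ.")
  clrs <- clr_tnf(rbind(ta, tb), c(la, lb))
  dt <- sqrt(sum((clrs[1, ] - clrs[2, ])^2)) / sqrt(length(ta))
  dc <- sqrt(sum((log1p(ca) - log1p(cb))^2)) / sqrt(length(ca))
  w * dt + (1 - w) * dc
}

# Full pairwise distance matrix for a feature table (dist object).
feature_dist <- function(features, w = 0.5) {
  tnfm <- clr_tnf(tnf_matrix(features), features$length)
  covm <- log1p(coverage_matrix(features))
  d <- w * dist(tnfm) / sqrt(ncol(tnfm)) +
    (1 - w) * dist(covm) / sqrt(ncol(covm))
  attr(d, "Labels") <- features$contig_id
  d
}

# Knee of the linkage-height curve. Merge heights are bimodal: a bulk of
# small within-genome merges and a tail of large between-genome merges.
# Otsu's criterion (maximum between-class variance) finds the split point
# robustly even when the largest single gap sits inside the tail; the cut
# is the midpoint of the boundary gap.
knee_cutoff <- function(heights) {
  hs <- sort(heights)
  n <- length(hs)
  if (n < 2L) return(max(hs) * 1.01)
  csum <- cumsum(hs)
  i <- seq_len(n - 1L)
  m1 <- csum[i] / i
  m2 <- (csum[n] - csum[i]) / (n - i)
  v <- (i / n) * (1 - i / n) * (m1 - m2)^2
  k <- which.max(v)
  (hs[k] + hs[k + 1L]) / 2
}

#' Cluster the contigs of one stratum
#'
#' Average-linkage agglomerative clustering on [contig_distance()], cut at
#' `linkage_cutoff` (knee-picked when `NULL`). Clusters whose summed contig
#' length falls below `min_bin_size` are reported with `provenance`
#' `"unbinned"`. Contigs are processed in lexicographic id order, making the
#' result independent of input order.
#'
#' @param features `rm_features` rows belonging to the stratum.
#' @param params [binning_params()].
#' @param label Prefix used for bin ids.
#' @return Tibble `contig_id`, `bin_id`, `provenance`.
#' @export
cluster_stratum <- function(features, params = binning_params(),
                            label = "s1") {
  if (nrow(features) == 0L) {
    return(tibble(contig_id = character(), bin_id = character(),
                  provenance = character()))
  }
  features <- arrange(features, .data$contig_id)
  if (nrow(features) == 1L) {
    cl <- 1L
  } else {
    d <- feature_dist(features, params$tnf_weight)
    hc <- hclust(d, method = "average")
    t <- params$linkage_cutoff %||% knee_cutoff(hc$height)
    cl <- cutree(hc, h = t)
  }
  out <- tibble(contig_id = features$contig_id,
                length = features$length, cluster = cl)
  sizes <- summarise(group_by(out, .data$cluster),
                     bp = sum(.data$length), .groups = "drop")
  keep <- sizes$cluster[sizes$bp >= params$min_bin_size]
  out$bin_id <- ifelse(out$cluster %in% keep,
                       sprintf("%s_b%02d", label, out$cluster), "unbinned")
  out$provenance <- ifelse(out$bin_id == "unbinned", "unbinned", "clustered")
  out[, c("contig_id", "bin_id", "provenance")]
}

#' Merge per-stratum bin sets into disjoint bins
#'
#' A contig clustered in several (overlapping) strata is assigned to the bin
#' whose medoid contig is nearest by [contig_distance()]; ties break by
#' bin id. Final bins are disjoint.
#'
#' @param bin_sets List of tibbles from [cluster_stratum()].
#' @param features Full `rm_features` tibble (for medoid distances).
#' @param w Compositional weight used for the medoid distances.
#' @return Tibble `contig_id`, `bin_id`, `provenance` with one row per contig.
#' @export
merge_strata <- function(bin_sets, features, w = 0.5) {
  all_bins <- bind_rows(bin_sets)
  binned <- filter(all_bins, .data$bin_id != "unbinned")
  dup_ids <- unique(binned$contig_id[duplicated(binned$contig_id)])
  if (length(dup_ids) > 0L) {
    medoids <- bin_medoids(binned, features, w)
    resolved <- vapply(dup_ids, function(cid) {
      cand <- sort(unique(binned$bin_id[binned$contig_id == cid]))
      ci <- features[features$contig_id == cid, ]
      dists <- vapply(cand, function(b) {
        mi <- features[features$contig_id == medoids[[b]], ]
        contig_distance(ci, mi, w)
      }, numeric(1))
      cand[which.min(dists)]  # which.min takes the first (lexicographic) tie
    }, character(1))
    keep_key <- paste(dup_ids, resolved)
    binned <- filter(binned,
                     !(.data$contig_id %in% dup_ids) |
                       paste(.data$contig_id, .data$bin_id) %in% keep_key)
    binned <- distinct(binned, .data$contig_id, .keep_all = TRUE)
  }
  unb <- filter(all_bins, .data$bin_id == "unbinned",
                !(.data$contig_id %in% binned$contig_id))
  unb <- distinct(unb, .data$contig_id, .keep_all = TRUE)
  arrange(bind_rows(binned, unb), .data$contig_id)
}

bin_medoids <- function(assignments, features, w = 0.5) {
  out <- list()
  for (b in sort(unique(assignments$bin_id))) {
    ids <- sort(assignments$contig_id[assignments$bin_id == b])
    sub <- features[match(ids, features$contig_id), ]
    if (length(ids) == 1L) { out[[b]] <- ids; next }
    d <- as.matrix(feature_dist(sub, w))
    out[[b]] <- ids[which.min(colSums(d))]
  }
  out
}

#' Bin contigs by composition and differential coverage
#'
#' The full binning stage: pre-partition contigs into abundance strata
#' ([prepartition()]), cluster each stratum by average linkage on the
#' combined compositional + differential-coverage distance
#' ([cluster_stratum()]), and resolve overlap duplicates ([merge_strata()]).
#' Bin ids are renumbered `bin_01`, `bin_02`, ... by decreasing summed
#' length.
#'
#' @param features An `rm_features` tibble.
#' @param params [binning_params()].
#' @return Tibble of class `rm_bins`: `contig_id`, `bin_id` (`"unbinned"`
#'   for leftovers), `provenance`.
#' @export
bin_contigs <- function(features, params = binning_params()) {
  strata <- prepartition(features, params$n_strata, params$stratum_overlap)
  sets <- lapply(sort(unique(strata$stratum)), function(s) {
    ids <- strata$contig_id[strata$stratum == s]
    cluster_stratum(features[features$contig_id %in% ids, ], params,
                    label = sprintf("s%d", s))
  })
  merged <- merge_strata(sets, features, params$tnf_weight)
  # renumber by decreasing bin length
  merged <- left_join(merged,
                      tibble(contig_id = features$contig_id,
                             length = features$length),
                      by = "contig_id")
  sizes <- summarise(group_by(filter(merged, .data$bin_id != "unbinned"),
                              .data$bin_id),
                     bp = sum(.data$length), .groups = "drop")
  sizes <- arrange(sizes, dplyr::desc(.data$bp), .data$bin_id)
  relabel <- setNames(sprintf("bin_%02d", seq_len(nrow(sizes))), sizes$bin_id)
  merged$bin_id <- ifelse(merged$bin_id == "unbinned", "unbinned",
                          relabel[merged$bin_id])
  out <- merged[, c("contig_id", "bin_id", "provenance")]
  structure(out, class = c("rm_bins", class(out)))
}

#' @export
print.rm_bins <- function(x, ...) {
  nb <- length(setdiff(unique(x$bin_id), "unbinned"))
  cat("<rm_bins> ", nb, " bin(s), ", sum(x$bin_id == "unbinned"),
      " unbinned contig(s)\n", sep = "")
  NextMethod()
}

#' GC/coverage scatter coloured by bin
#'
#' @param object An `rm_bins` tibble.
#' @param features The `rm_features` tibble the bins were built from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rm_bins <- function(object, features, ...) {
  df <- left_join(as_tibble(object),
                  tibble(contig_id = features$contig_id,
                         gc = features$gc,
                         mean_cov = vapply(features$coverage, mean,
                                           numeric(1))),
                  by = "contig_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_cov, y = .data$gc,
                                   colour = .data$bin_id)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "Mean coverage (fold, log1p scale)", y = "GC fraction",
                  colour = "Bin") +
    ggplot2::theme_minimal()
}
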