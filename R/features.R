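#' Canonical tetranucleotide alphabet
#'
#' Contig strand is arbitrary, so tetramer counts are collapsed onto the
#' lexicographically smaller of each 4-mer and its reverse complement. The
#' 256 DNA 4-mers contain 16 reverse-complement palindromes, leaving
#' (256 - 16) / 2 + 16 = 136 canonical tetramers.
#'
#' @return Character vector of the 136 canonical tetramers, sorted.
#' @export
#' @examples
#' length(canonical_tetramers()) # 136
canonical_tetramers <- function() {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  sort(unique(pmin(kmers, rc)))
}

# cache: the alphabet never changes
.tetramer_env <- new.env(parent = emptyenv())

tetramer_map <- function() {
  if (is.null(.tetramer_env$map)) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    .tetramer_env$map <- setNames(pmin(kmers, rc), kmers)
    .tetramer_env$canon <- sort(unique(.tetramer_env$map))
  }
  .tetramer_env$map
}

#' Canonical tetranucleotide frequencies of a sequence
#'
#' Slides a 4-bp window with step 1; windows containing characters outside
#' A/C/G/T are skipped. Counts are collapsed onto the canonical
#' (reverse-complement-smaller) tetramer and normalised to frequencies, so
#' `tnf(s)` is identical for a contig and its reverse complement.
#'
#' @param sequence A single nucleotide string (case-insensitive).
#' @return Named numeric vector of length 136 summing to 1.
#' @export
#' @examples
#' tnf("AAAAAA")[["AAAA"]] # 1
tnf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- Biostrings::DNAString(toupper(sequence))
  counts <- Biostrings::oligonucleotideFrequency(s, width = 4L, step = 1L)
  total <- sum(counts)
  if (total == 0) {
    abort("No valid A/C/G/T tetramer window in sequence; contig cannot be profiled.")
  }
  map <- tetramer_map()
  canon <- .tetramer_env$canon
  collapsed <- vapply(split(counts[names(map)], map), sum, numeric(1))
  out <- setNames(numeric(length(canon)), canon)
  out[names(collapsed)] <- collapsed
  out / total
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param sequence A single nucleotide string (case-insensitive).
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  s <- Biostrings::DNAString(toupper(sequence))
  af <- Biostrings::alphabetFrequency(s)
  denom <- sum(af[c("A", "C", "G", "T")])
  if (denom == 0) abort("Sequence has no unambiguous A/C/G/T bases.")
  sum(af[c("G", "C")]) / denom
}

#' Build the per-contig feature table
#'
#' Joins contig sequences with a per-sample coverage table into the feature
#' tibble consumed by [bin_contigs()]: length, GC, canonical tetranucleotide
#' frequency vector (list-column) and coverage profile (list-column, sample
#' order taken from the coverage table header).
#'
#' Contigs present in the FASTA but missing from the coverage table get an
#' all-zero profile with a warning; coverage rows without a matching contig
#' are dropped with a warning.
#'
#' @param contigs FASTA path, named character vector, or `DNAStringSet`.
#' @param coverage TSV path (`contig` column then one column per sample) or a
#'   data frame of the same shape.
#' @return A tibble of class `rm_features` with columns `contig_id`, `length`,
#'   `gc`, `tnf` (list of 136-vectors), `coverage` (list of named
#'   per-sample depths); attribute `samples` holds the sample names.
#' @export
build_features <- function(contigs, coverage) {
  seqs <- as_seq_chr(contigs, "DNA")
  cov <- read_coverage(coverage)
  samples <- setdiff(names(cov), "contig")

  missing_in_fasta <- setdiff(cov$contig, names(seqs))
  if (length(missing_in_fasta) > 0L) {
    warn(paste0(length(missing_in_fasta),
                " coverage row(s) without a contig sequence dropped (e.g. ",
                missing_in_fasta[1L], ")."))
    cov <- cov[cov$contig %in% names(seqs), , drop = FALSE]
  }
  missing_in_cov <- setdiff(names(seqs), cov$contig)
  if (length(missing_in_cov) > 0L) {
    warn(paste0(length(missing_in_cov),
                " contig(s) absent from the coverage table treated as zero",
                " coverage (e.g. ", missing_in_cov[1L], ")."))
  }

  cov_mat <- as.matrix(cov[, samples, drop = FALSE])
  rownames(cov_mat) <- cov$contig
  if (any(cov_mat < 0)) abort("Coverage values must be non-negative.")

  # contigs with no valid A/C/G/T window cannot be profiled for binning
  profiled <- vapply(seqs, function(s)
    !inherits(try(tnf(s), silent = TRUE), "try-error"), logical(1))
  if (any(!profiled)) {
    warn(paste0(sum(!profiled), " contig(s) without a valid tetramer window",
                " excluded (e.g. ", names(seqs)[!profiled][1L], ")."))
    seqs <- seqs[profiled]
  }
  ids <- names(seqs)
  covs <- lapply(ids, function(id) {
    if (id %in% rownames(cov_mat)) setNames(as.numeric(cov_mat[id, ]), samples)
    else setNames(numeric(length(samples)), samples)
  })
  out <- tibble(
    contig_id = ids,
    length = nchar(seqs),
    gc = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE),
    tnf = lapply(seqs, tnf),
    coverage = covs
  )
  out <- arrange(out, .data$contig_id)
  structure(out, samples = samples,
            class = c("rm_features", class(out)))
}

read_coverage <- function(coverage) {
  if (is.character(coverage) && length(coverage) == 1L) {
    cov <- readr::read_tsv(coverage, show_col_types = FALSE, progress = FALSE)
  } else if (is.data.frame(coverage)) {
    cov <- as_tibble(coverage)
  } else {
    abort("`coverage` must be a TSV path or a data frame.")
  }
  if (names(cov)[1L] != "contig") names(cov)[1L] <- "contig"
  if (ncol(cov) < 2L) abort("Coverage table needs at least one sample column.")
  if (anyDuplicated(cov$contig)) {
    abort(paste0("Duplicate contig id in coverage table: ",
                 cov$contig[duplicated(cov$contig)][1L]))
  }
  bad <- !vapply(cov[-1L], is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("Non-numeric coverage column: ", names(cov)[-1L][bad][1L]))
  }
  cov
}

#' @export
print.rm_features <- function(x, ...) {
  cat("<rm_features> ", nrow(x), " contigs, ",
      length(attr(x, "samples")), " sample(s)\n", sep = "")
  NextMethod()
}

coverage_matrix <- function(features) {
  do.call(rbind, features$coverage)
}

tnf_matrix <- function(features) {
  do.call(rbind, features$tnf)
}

#' Write / read a feature table as TSV
#'
#' Flat layout: `contig`, `length`, `gc`, one `cov_<sample>` column per
#' sample, then `tnf_<tetramer>` columns. Round-trips exactly via
#' [read_features()].
#'
#' @param features An `rm_features` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  samples <- attr(features, "samples")
  cov <- coverage_matrix(features)
  colnames(cov) <- paste0("cov_", samples)
  tnfm <- tnf_matrix(features)
  colnames(tnfm) <- paste0("tnf_", colnames(tnfm))
  flat <- bind_cols_safe(
    tibble(contig = features$contig_id, length = features$length,
           gc = features$gc),
    as_tibble(cov), as_tibble(tnfm)
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

bind_cols_safe <- function(...) {
  as_tibble(do.call(cbind, lapply(list(...), as.data.frame)))
}

#' @rdname write_features
#' @param path Path of a TSV written by [write_features()].
#' @export
read_features <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- sub("^cov_", "", grep("^cov_", names(flat), value = TRUE))
  tetra <- sub("^tnf_", "", grep("^tnf_", names(flat), value = TRUE))
  out <- tibble(
    contig_id = flat$contig,
    length = flat$length,
    gc = flat$gc,
    tnf = lapply(seq_len(nrow(flat)), function(i)
      setNames(as.numeric(flat[i, paste0("tnf_", tetra)]), tetra)),
    coverage = lapply(seq_len(nrow(flat)), function(i)
      setNames(as.numeric(flat[i, paste0("cov_", samples)]), samples))
  )
  structure(out, samples = samples, class = c("rm_features", class(out)))
}

#' Scatter of contig GC against mean coverage
#'
#' @param object An `rm_features` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rm_features <- function(object, ...) {
  df <- tibble(
    gc = object$gc,
    mean_cov = vapply(object$coverage, mean, numeric(1)),
    length = object$length
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_cov, y = .data$gc,
                                   size = .data$length)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "Mean coverage (fold, log1p scale)", y = "GC fraction",
                  size = "Contig bp") +
    ggplot2::theme_minimal()
}
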