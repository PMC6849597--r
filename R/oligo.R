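#' Reverse complement of a DNA sequence
#'
#' Strict A/C/G/T only: degenerate bases are rejected rather than expanded,
#' matching non-degenerate primer/probe design. A FISH probe is the reverse
#' complement of a forward primer at the same locus.
#'
#' @param sequence Single A/C/G/T string.
#' @return Reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("GAGGTTTTAACAGACCTTGG") # the matching probe sequence
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- setdiff(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    abort(paste0("Character outside A/C/G/T: ", bad[1L]))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find clade-specific inserts in a multiple alignment
#'
#' Maximal runs of alignment columns that are residues in every target
#' sequence and gaps in every non-target — signature insertions private to
#' the target clade, exploitable for primers and probes.
#'
#' @param alignment Aligned FASTA path, named character vector of equal
#'   lengths (gaps `-` or `.`), or `DNAStringSet`.
#' @param target_ids Ids of the target clade within the alignment.
#' @param min_len Minimum insert length in columns (default 5).
#' @return Tibble `start` (1-based alignment column), `length`, `targets`;
#'   sorted by start.
#' @export
find_inserts <- function(alignment, target_ids, min_len = 5) {
  aln <- as_seq_chr(alignment, "DNA")
  if (length(unique(nchar(aln))) != 1L) {
    abort("Ragged alignment: sequences have unequal aligned lengths.")
  }
  if (!all(target_ids %in% names(aln))) {
    abort("`target_ids` must all be present in the alignment.")
  }
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  is_gap <- mat %in% c("-", ".")
  dim(is_gap) <- dim(mat)
  tgt <- rownames(mat) %in% target_ids
  if (all(tgt)) abort("At least one non-target sequence is required.")
  insert_col <- apply(!is_gap[tgt, , drop = FALSE], 2, all) &
    apply(is_gap[!tgt, , drop = FALSE], 2, all)
  r <- rle(insert_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], length = r$lengths[keep],
         targets = rep(list(sort(target_ids)), sum(keep)))
}

# fast scalar reverse complement for inner loops (A/C/G/T only)
rc_chr <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
}

# Minimum Hamming distance of `oligo` over all ungapped windows of `seq`,
# forward strand only. NA if seq shorter than oligo.
min_mismatch_scan <- function(oligo, seq) {
  if (nchar(seq) < nchar(oligo)) return(NA_integer_)
  min_hamming(utf8ToInt(oligo), utf8ToInt(seq))
}

#' Minimum mismatches of an oligo against each sequence
#'
#' Ungapped sliding comparison on both strands; per sequence, the minimum
#' Hamming distance over all windows. Sequences shorter than the oligo are
#' reported as `NA` (no site).
#'
#' @param oligo A/C/G/T string.
#' @param sequences FASTA path, named character vector, or `DNAStringSet`.
#' @return Tibble `sequence_id`, `min_mismatches`.
#' @export
oligo_specificity <- function(oligo, sequences) {
  seqs <- toupper(as_seq_chr(sequences, "DNA"))
  seqs <- vapply(seqs, function(s) gsub("[-.]", "", s), character(1))
  o <- toupper(oligo)
  orc <- rc_chr(o)
  mm <- vapply(seqs, function(s) {
    m <- suppressWarnings(min(min_mismatch_scan(o, s),
                              min_mismatch_scan(orc, s), na.rm = TRUE))
    if (is.infinite(m)) NA_integer_ else as.integer(m)
  }, integer(1))
  tibble(sequence_id = names(seqs), min_mismatches = unname(mm))
}

#' Design clade-specific oligonucleotides
#'
#' Candidates are k-mers that occur exactly (0 mismatches, either strand) in
#' every target sequence and have at least `min_mismatch` mismatches to
#' their best ungapped match (either strand) in every non-target. Ranked by
#' worst-case non-target mismatch count (descending), ties by position in
#' the first target, then lexicographically.
#'
#' @param targets,nontargets FASTA paths, named character vectors, or
#'   `DNAStringSet`s (gaps are stripped).
#' @param k Oligo length in nt (15-30), default 20.
#' @param min_mismatch Minimum mismatches required against every non-target
#'   (default 2).
#' @return Tibble of class `rm_oligos`: `name`, `sequence`, `orientation`,
#'   `position` (in the first target), `worst_case_mismatches`.
#' @export
design_oligos <- function(targets, nontargets, k = 20, min_mismatch = 2) {
  if (k < 15 || k > 30) abort("`k` must be in [15, 30].")
  tg <- toupper(as_seq_chr(targets, "DNA"))
  nt <- toupper(as_seq_chr(nontargets, "DNA"))
  if (length(tg) == 0L || length(nt) == 0L) {
    abort("Both target and non-target sets must be non-empty.")
  }
  tg <- vapply(tg, function(s) gsub("[-.]", "", s), character(1))
  nt <- vapply(nt, function(s) gsub("[-.]", "", s), character(1))
  first <- tg[[1L]]
  if (nchar(first) < k) abort("Target sequence shorter than `k`.")
  starts <- seq_len(nchar(first) - k + 1L)
  kmers <- substring(first, starts, starts + k - 1L)
  cand <- tibble(sequence = kmers, position = starts)
  cand <- cand[!grepl("[^ACGT]", cand$sequence), , drop = FALSE]
  cand <- cand[!duplicated(cand$sequence), , drop = FALSE]
  # exact presence (either strand) in every target
  in_all <- vapply(cand$sequence, function(km) {
    rc <- rc_chr(km)
    all(vapply(tg, function(s)
      grepl(km, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1)))
  }, logical(1))
  cand <- cand[in_all, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(structure(tibble(name = character(), sequence = character(),
                            orientation = character(), position = integer(),
                            worst_case_mismatches = integer()),
                     class = c("rm_oligos", class(tibble()))))
  }
  worst <- vapply(cand$sequence, function(km) {
    mm <- oligo_specificity(km, nt)$min_mismatches
    if (anyNA(mm)) mm[is.na(mm)] <- nchar(km)
    min(mm)
  }, numeric(1))
  cand$worst_case_mismatches <- as.integer(worst)
  cand <- cand[cand$worst_case_mismatches >= min_mismatch, , drop = FALSE]
  cand <- cand[order(-cand$worst_case_mismatches, cand$position,
                     cand$sequence), , drop = FALSE]
  out <- tibble(
    name = sprintf("oligo_%02d", seq_len(nrow(cand))),
    sequence = cand$sequence,
    orientation = "forward",
    position = cand$position,
    worst_case_mismatches = cand$worst_case_mismatches
  )
  structure(out, class = c("rm_oligos", class(out)))
}

#' Global-identity screen of a query against candidate sequences
#'
#' Needleman-Wunsch with free end gaps; identity is matches over alignment
#' columns. Candidates at or above `threshold` % are hits — the criterion
#' used to screen databases for sequences belonging to the target clade.
#'
#' @param query Single nucleotide string.
#' @param candidates FASTA path, named character vector, or `DNAStringSet`.
#' @param threshold Identity threshold in % (default 98).
#' @return Tibble `sequence_id`, `identity_pct`, `hit`.
#' @export
identity_screen <- function(query, candidates, threshold = 98) {
  stopifnot(nzchar(query))
  seqs <- toupper(as_seq_chr(candidates, "DNA"))
  seqs <- vapply(seqs, function(s) gsub("[-.]", "", s), character(1))
  q <- Biostrings::DNAString(toupper(gsub("[-.]", "", query)))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                      mismatch = -1)
  ident <- vapply(seqs, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::DNAString(s), type = "overlap",
      substitutionMatrix = sub_mat, gapOpening = 5, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    if (cols == 0) 0 else 100 * Biostrings::nmatch(aln) / cols
  }, numeric(1))
  tibble(sequence_id = names(seqs), identity_pct = unname(ident),
         hit = unname(ident >= threshold))
}
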