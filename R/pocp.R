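# Karlin-Altschul parameters for gapped BLOSUM62, gap open 11 / extend 1
# (the standard values used by protein database search).
.ka_lambda <- 0.267
.ka_K <- 0.041

aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

check_protein <- function(p, what = "sequence") {
  if (!is.character(p) || length(p) != 1L || !nzchar(p)) {
    abort(paste0("Empty or invalid protein ", what, "."))
  }
  bad <- setdiff(strsplit(toupper(p), "")[[1]], aa_alphabet())
  if (length(bad) > 0L) {
    abort(paste0("Character outside the amino-acid alphabet: ", bad[1L]))
  }
  toupper(p)
}

#' Local protein alignment with search-style statistics
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1). Identity is matches over alignment columns; aligned fraction
#' is the share of query residues inside the alignment; the e-value follows
#' Karlin-Altschul statistics with the subject proteome's residue count as
#' database size — the pairwise-proteome search the conserved-protein metric
#' assumes.
#'
#' @param query,subject Amino-acid strings.
#' @param db_residues Residue count of the subject proteome (defaults to the
#'   subject's own length).
#' @return List: `score`, `identity_pct`, `aligned_fraction`, `evalue`.
#' @export
align_pair <- function(query, subject, db_residues = nchar(subject)) {
  query <- check_protein(query, "query")
  subject <- check_protein(subject, "subject")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = get("BLOSUM62"),
    gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(aln)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- if (cols > 0) 100 * Biostrings::nmatch(aln) / cols else 0
  qwidth <- Biostrings::width(Biostrings::pattern(aln))
  afrac <- qwidth / nchar(query)
  evalue <- .ka_K * nchar(query) * db_residues * exp(-.ka_lambda * s)
  list(score = s, identity_pct = ident, aligned_fraction = afrac,
       evalue = evalue)
}

#' Count conserved proteins between two proteomes
#'
#' A protein of proteome 1 is conserved iff some protein of proteome 2 gives
#' a local alignment with e-value below `evalue_max`, identity above
#' `identity_min` %, and alignable region above `afrac_min` of the query
#' length; symmetrically for proteome 2. Proteins shorter than `min_len`
#' residues are skipped with a warning (their e-values are spurious) and do
#' not count toward the totals.
#'
#' @param p1,p2 Named character vectors of amino-acid sequences (or FASTA
#'   paths / `AAStringSet`s).
#' @param evalue_max,identity_min,afrac_min Conservation thresholds
#'   (defaults 1e-5, 40, 0.5).
#' @param min_len Minimum protein length considered (default 30 aa).
#' @return List: `C1`, `C2`, `T1`, `T2`.
#' @export
count_conserved <- function(p1, p2, evalue_max = 1e-5, identity_min = 40,
                            afrac_min = 0.5, min_len = 30) {
  p1 <- as_seq_chr(p1, "AA"); p2 <- as_seq_chr(p2, "AA")
  if (length(p1) == 0L || length(p2) == 0L) {
    abort("Both proteomes must be non-empty.")
  }
  drop1 <- nchar(p1) < min_len; drop2 <- nchar(p2) < min_len
  if (any(drop1) || any(drop2)) {
    warn(paste0(sum(drop1) + sum(drop2), " protein(s) shorter than ",
                min_len, " aa skipped."))
    p1 <- p1[!drop1]; p2 <- p2[!drop2]
  }
  db2 <- sum(nchar(p2)); db1 <- sum(nchar(p1))
  conserved <- function(queries, subjects, db) {
    vapply(queries, function(q) {
      for (s in subjects) {
        a <- align_pair(q, s, db_residues = db)
        if (a$evalue < evalue_max && a$identity_pct > identity_min &&
            a$aligned_fraction > afrac_min) return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  list(C1 = sum(conserved(p1, p2, db2)), C2 = sum(conserved(p2, p1, db1)),
       T1 = length(p1), T2 = length(p2))
}

#' Percentage of conserved proteins (POCP) between two proteomes
#'
#' `100 * (C1 + C2) / (T1 + T2)` with C/T from [count_conserved()]. Values
#' above 50% between all members of a group delineate a prokaryotic genus;
#' a genome below the cutoff against every member of related genera is a
#' novel-genus candidate.
#'
#' @inheritParams count_conserved
#' @param ... Passed to [count_conserved()].
#' @return One-row tibble of class `rm_pocp`: `C1`, `C2`, `T1`, `T2`,
#'   `value` (%).
#' @export
pocp <- function(p1, p2, ...) {
  cc <- count_conserved(p1, p2, ...)
  if (cc$T1 + cc$T2 == 0) abort("No proteins to compare.")
  out <- tibble(C1 = cc$C1, C2 = cc$C2, T1 = cc$T1, T2 = cc$T2,
                value = 100 * (cc$C1 + cc$C2) / (cc$T1 + cc$T2))
  structure(out, class = c("rm_pocp", class(out)))
}

#' @export
tidy.rm_pocp <- function(x, ...) as_tibble(x)

#' @export
glance.rm_pocp <- function(x, ...) tibble(value = x$value)

#' All-pairs POCP matrix
#'
#' @param proteomes Named list of proteomes (named character vectors of
#'   amino-acid sequences).
#' @param ... Passed to [count_conserved()].
#' @return Symmetric numeric matrix (%, diagonal 100).
#' @export
pocp_matrix <- function(proteomes, ...) {
  n <- length(proteomes)
  ids <- names(proteomes) %||% sprintf("proteome_%d", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- pocp(proteomes[[i]], proteomes[[j]], ...)$value
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Genus groups from a POCP matrix
#'
#' Maximal groups in which every pairwise POCP value exceeds `cutoff`
#' (complete-linkage reading of the genus definition, which quantifies over
#' all pairs). Groups are peeled off greedily: the largest clique first,
#' ties broken lexicographically, so the grouping is deterministic. Genomes
#' in no multi-member group are singleton novel-genus candidates.
#'
#' @param m Symmetric POCP matrix (%).
#' @param cutoff Genus cutoff (%), default 50.
#' @return Tibble `genome_id`, `group` (integer), `singleton` (flag).
#' @export
genus_clusters <- function(m, cutoff = 50) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-6))) {
    abort("POCP matrix is asymmetric beyond tolerance 1e-6.")
  }
  ids <- rownames(m) %||% sprintf("g%d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  adj <- m > cutoff
  diag(adj) <- TRUE
  remaining <- sort(ids)
  group <- setNames(integer(length(ids)), ids)
  gi <- 0L
  while (length(remaining) > 0L) {
    cl <- best_clique(adj[remaining, remaining, drop = FALSE])
    gi <- gi + 1L
    group[cl] <- gi
    remaining <- setdiff(remaining, cl)
  }
  g <- unname(group[ids])
  sizes <- as.integer(table(group)[match(as.character(g),
                                         names(table(group)))])
  tibble(genome_id = ids, group = g, singleton = sizes == 1L)
}

# Largest clique of a small boolean adjacency matrix; ties by lexicographic
# member concatenation. Exhaustive over subsets of each vertex's
# neighbourhood — fine at genus-table scale.
best_clique <- function(adj) {
  ids <- sort(rownames(adj))
  best <- ids[1L]
  grow <- function(clique, candidates) {
    if (length(candidates) == 0L) {
      if (length(clique) > length(best) ||
          (length(clique) == length(best) &&
           paste(sort(clique), collapse = ",") <
             paste(sort(best), collapse = ","))) {
        best <<- clique
      }
      return(invisible())
    }
    v <- candidates[1L]
    grow(c(clique, v),
         candidates[candidates %in% rownames(adj)[adj[v, ]] &
                      candidates != v])
    grow(clique, candidates[-1L])
    invisible()
  }
  grow(character(0), ids)
  sort(best)
}

#' POCP matrix heat map
#'
#' @param m Symmetric POCP matrix.
#' @param cutoff Genus cutoff drawn into the fill scale.
#' @return A ggplot.
#' @export
plot_pocp_matrix <- function(m, cutoff = 50) {
  df <- as_tibble(as.data.frame(as.table(m)))
  names(df) <- c("a", "b", "pocp")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$pocp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pocp)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = cutoff, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "POCP (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
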