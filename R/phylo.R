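#' Observed proportion of differing sites (p-distance)
#'
#' Pairwise deletion: columns where either sequence has a gap or ambiguity
#' are excluded, then differing sites over compared sites.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("Aligned lengths differ.")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("No comparable (ungapped, unambiguous) sites.")
  sum(av[ok] != bv[ok]) / sum(ok)
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) * log(1 - 4p/3)`, converting the observed proportion of
#' differing sites into an expected number of substitutions per site under
#' equal base frequencies and equal substitution rates. Undefined at
#' saturation (p >= 0.75).
#'
#' @param p Observed p-distance(s) in \[0, 0.75).
#' @return Corrected distance(s), always >= p.
#' @export
#' @examples
#' jc_correct(0.02) # 0.020272...
jc_correct <- function(p) {
  if (any(p < 0)) abort("`p` must be >= 0.")
  if (any(p >= 0.75)) {
    abort("Saturated p-distance (p >= 0.75): Jukes-Cantor undefined.")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' @param alignment Aligned FASTA path, named character vector, or
#'   `DNAStringSet`.
#' @param saturated Replacement distance for saturated pairs (`NULL` =
#'   error on saturation).
#' @return Symmetric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(alignment, saturated = NULL) {
  aln <- as_seq_chr(alignment, "DNA")
  n <- length(aln)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      p <- p_distance(aln[[i]], aln[[j]])
      d <- if (p >= 0.75) {
        if (is.null(saturated)) {
          abort("Saturated p-distance (p >= 0.75): Jukes-Cantor undefined.")
        }
        saturated
      } else jc_correct(p)
      m[i, j] <- d; m[j, i] <- d
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimising
#' the Q criterion (ties broken by the lexicographically smallest taxon
#' pair), with branch lengths from the NJ formulas; negative estimates are
#' clamped to 0 with a warning. Returns an unrooted `ape::phylo`.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) abort("Neighbor joining needs at least 3 taxa.")
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  }
  if (max(abs(D - t(D))) > 1e-12) abort("Distance matrix is asymmetric.")
  labels <- rownames(D)
  # working copy; node "labels" are newick fragments
  frag <- setNames(labels, labels)
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # ties: lexicographically smallest sorted taxon pair
    hits <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    keys <- apply(hits, 1, function(ij) {
      p <- sort(rownames(D)[ij])
      paste(p, collapse = "\r")
    })
    pick <- hits[order(keys)[1L], ]
    i <- min(pick); j <- max(pick)
    di <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    dj <- D[i, j] - di
    new_d <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)",
                        frag[rownames(D)[i]], bl(di),
                        frag[rownames(D)[j]], bl(dj))
    new_name <- paste0("node_", nn)
    keep <- rownames(D)[-c(i, j)]
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    rownames(D2) <- colnames(D2) <- c(keep, new_name)
    D <- D2
    frag <- c(frag[keep], setNames(new_frag, new_name))
  }
  # final three-taxon star: closed-form three-point branch lengths
  ids <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[ids[1]], bl(la), frag[ids[2]], bl(lb),
                 frag[ids[3]], bl(lc))
  if (clamped) warn("Negative NJ branch length(s) clamped to 0.")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with Jukes-Cantor distances and bootstrap support
#'
#' Builds the full-data tree from Jukes-Cantor-corrected p-distances
#' (pairwise deletion), then resamples alignment columns with replacement
#' `n_replicates` times, rebuilds the tree per replicate, and attaches to
#' each internal edge the percentage of replicates containing that split.
#'
#' @param alignment Aligned FASTA path, named character vector, or
#'   `DNAStringSet`.
#' @param n_replicates Bootstrap replicates (>= 1); 2000 for a
#'   publication-grade tree, fewer for quick checks.
#' @param seed Integer seed; identical seeds give identical supports.
#' @param saturated Replacement distance for saturated pairs in replicates
#'   (resampling can push p past 0.75 even when the full data are fine).
#' @return A `phylo` object with `node.label` holding support percentages
#'   (root label empty).
#' @export
bootstrap_support <- function(alignment, n_replicates = 2000, seed = 1,
                              saturated = 3) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  aln <- as_seq_chr(alignment, "DNA")
  tree <- nj_tree(jc_distance_matrix(aln, saturated = saturated))
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  L <- ncol(mat)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      suppressWarnings(nj_tree(jc_distance_matrix(res, saturated = saturated)))
    })
  })
  counts <- suppressWarnings(ape::prop.clades(tree, reps, rooted = FALSE))
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_replicates, 1)
  tree$node.label <- as.character(support)
  tree$node.label[1L] <- ""  # root of the unrooted representation
  tree
}

#' Write a tree as newick with supports as internal node labels
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @param digits Branch-length digits (default 6).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
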