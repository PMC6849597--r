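# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration / brute force / textbook DP) and share no
# code with the package internals.

# Tetranucleotide frequencies by direct window enumeration.
tnf_oracle <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  canon <- canonical_tetramers()
  counts <- setNames(numeric(length(canon)), canon)
  total <- 0
  rc1 <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  for (i in seq_len(max(n - 3, 0))) {
    w <- substr(s, i, i + 3)
    if (grepl("[^ACGT]", w)) next
    key <- min(w, rc1(w))
    counts[key] <- counts[key] + 1
    total <- total + 1
  }
  if (total == 0) return(NULL)
  counts / total
}

# N50 by scanning candidate lengths from the largest down: the first contig
# length whose at-least-that-long contigs cover half the assembly.
n50_oracle <- function(lengths) {
  half <- sum(lengths) / 2
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
}

# Textbook affine-gap Smith-Waterman (gap of length L costs open + L * ext)
# under BLOSUM62, with traceback for identity. O(n*m), toy scale only.
sw_oracle <- function(q, s, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62")
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (consumes query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes subject)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- B[qv[i - 1], sv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + sub
      if (M[i, j] < 0) M[i, j] <- NEG
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  M[M < 0] <- 0
  score <- max(M)
  hit <- which(M == score, arr.ind = TRUE)[1, ]
  # traceback for matches / columns
  i <- hit[1]; j <- hit[2]; state <- "M"
  matches <- 0; cols <- 0
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] <= 0) break
      sub <- B[qv[i - 1], sv[j - 1]]
      cols <- cols + 1
      if (qv[i - 1] == sv[j - 1]) matches <- matches + 1
      prev <- M[i, j] - sub
      if (abs(prev) < 1e-9 && !(i > 2 && j > 2 &&
          (abs(M[i-1,j-1]-prev)<1e-9 || abs(Ix[i-1,j-1]-prev)<1e-9 ||
           abs(Iy[i-1,j-1]-prev)<1e-9))) { i <- i-1; j <- j-1; break }
      if (abs(M[i - 1, j - 1] - prev) < 1e-9) state <- "M"
      else if (abs(Ix[i - 1, j - 1] - prev) < 1e-9) state <- "Ix"
      else state <- "Iy"
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      cols <- cols + 1
      if (abs(Ix[i, j] - (M[i - 1, j] - open - ext)) < 1e-9) state <- "M"
      i <- i - 1
    } else {
      cols <- cols + 1
      if (abs(Iy[i, j] - (M[i, j - 1] - open - ext)) < 1e-9) state <- "M"
      j <- j - 1
    }
  }
  list(score = score,
       identity_pct = if (cols > 0) 100 * matches / cols else 0,
       unique_opt = sum(abs(M - score) < 1e-9) == 1)
}

# Exact upper binomial tail P(X >= k) by summation.
binom_tail_oracle <- function(k, m, p) {
  if (k <= 0) return(1)
  sum(vapply(k:m, function(x) choose(m, x) * p^x * (1 - p)^(m - x),
             numeric(1)))
}

# Random additive tree -> exact leaf-to-leaf path-length matrix via ape.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, 0.05, 0.5))
  list(tree = tr, D = cophenetic(tr))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
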