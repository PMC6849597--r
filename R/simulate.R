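#' Simulate bacterial genome sequences
#'
#' Each genome is an order-2 Markov chain over A/C/G/T with its own
#' independently seeded transition structure, so tetranucleotide composition
#' separates lineages the way it does between real genomes. GC is steered to
#' a per-genome target; realised GC lands within about +/-0.02 of it.
#'
#' @param n_genomes Number of genomes (>= 0).
#' @param mean_length Mean genome length in bp (>= 50000); individual lengths
#'   are jittered uniformly by +/-10%.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param gc_range Range the per-genome GC targets are drawn from.
#' @return Tibble with columns `genome_id`, `length`, `gc_target`, `sequence`.
#' @export
simulate_genomes <- function(n_genomes, mean_length = 1e5, seed = 1,
                             gc_range = c(0.35, 0.65)) {
  if (n_genomes < 0) abort("`n_genomes` must be >= 0.")
  if (n_genomes == 0) {
    return(tibble(genome_id = character(), length = integer(),
                  gc_target = numeric(), sequence = character()))
  }
  if (mean_length < 5e4) abort("`mean_length` must be >= 50000 bp.")
  with_seed(seed, {
    lens <- as.integer(round(mean_length * runif(n_genomes, 0.9, 1.1)))
    gcs <- runif(n_genomes, gc_range[1], gc_range[2])
    seqs <- vapply(seq_len(n_genomes), function(g)
      markov_sequence(lens[g], gcs[g]), character(1))
  })
  tibble(
    genome_id = sprintf("genome_%03d", seq_len(n_genomes)),
    length = lens,
    gc_target = gcs,
    sequence = seqs
  )
}

# Order-2 Markov chain with per-genome random transition preferences. The
# GC tilt of the emission weights is calibrated against the chain's
# stationary distribution so realised GC tracks the target closely.
markov_sequence <- function(len, gc_target) {
  bases <- c("A", "C", "G", "T")
  # 16 contexts x 4 next-base weights; exponentiated noise keeps them positive
  # and genome-specific.
  pref <- matrix(exp(rnorm(16 * 4, sd = 0.7)), nrow = 16)
  trans <- calibrate_gc(pref, gc_target)
  init <- sample.int(4L, 2L, replace = TRUE)
  u <- runif(len)
  cum <- t(apply(trans, 1, cumsum))
  out <- markov_walk(cum, init, u)
  paste(bases[out], collapse = "")
}

# Multiply the G/C emission weights by a tilt factor and bisect it until the
# stationary GC of the order-2 chain (a 16-state chain over dinucleotide
# contexts) matches the target.
calibrate_gc <- function(pref, gc_target, tol = 1e-4) {
  stationary_gc <- function(f) {
    w <- pref * rep(c(1, f, f, 1), each = 16)
    trans <- w / rowSums(w)
    # context (b1, b2) -> (b2, b3): P[ctx, ctx'] = trans[ctx, b3]
    P <- matrix(0, 16, 16)
    for (ctx in 1:16) {
      b2 <- (ctx - 1L) %% 4L + 1L
      for (b3 in 1:4) P[ctx, (b2 - 1L) * 4L + b3] <- trans[ctx, b3]
    }
    pi <- rep(1 / 16, 16)
    for (i in 1:200) pi <- pi %*% P
    pi <- as.numeric(pi / sum(pi))
    b2_marg <- tapply(pi, (seq_len(16) - 1L) %% 4L + 1L, sum)
    list(gc = b2_marg[[2]] + b2_marg[[3]], trans = trans)
  }
  lo <- 0.02; hi <- 50
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    g <- stationary_gc(mid)
    if (abs(g$gc - gc_target) < tol) break
    if (g$gc < gc_target) lo <- mid else hi <- mid
  }
  g$trans
}

#' Fragment genomes into contigs
#'
#' Tiles each genome left to right with non-overlapping fragments of length
#' uniform in `[min_len, max_len]`; a final fragment shorter than `min_len`
#' is dropped (assembly is not simulated — contigs are clean genome pieces).
#'
#' @param genomes Tibble from [simulate_genomes()].
#' @param min_len,max_len Contig length bounds in bp; `min_len` >= 1000.
#' @param seed Integer seed.
#' @return List with `contigs` (named character vector of sequences) and
#'   `truth` (tibble `contig_id`, `genome_id`, `start`, `end`).
#' @export
fragment_genomes <- function(genomes, min_len = 1500, max_len = 50000,
                             seed = 1) {
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  if (min_len < 1000) abort("`min_len` must be >= 1000 bp (composition floor).")
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genomes)), function(g) {
      glen <- genomes$length[g]
      starts <- integer(0); ends <- integer(0); pos <- 1L
      while (pos <= glen) {
        L <- if (min_len == max_len) min_len else
          as.integer(round(runif(1, min_len, max_len)))
        end <- min(pos + L - 1L, glen)
        if (end - pos + 1L >= min_len) {
          starts <- c(starts, pos); ends <- c(ends, end)
        }
        pos <- end + 1L
      }
      if (length(starts) == 0L) return(NULL)
      tibble(genome_id = genomes$genome_id[g], start = starts, end = ends)
    })
  })
  truth <- bind_rows(pieces)
  truth <- mutate(group_by(truth, .data$genome_id),
                  contig_id = sprintf("%s_c%03d", .data$genome_id,
                                      dplyr::row_number()))
  truth <- ungroup(truth)[, c("contig_id", "genome_id", "start", "end")]
  seq_by_genome <- setNames(genomes$sequence, genomes$genome_id)
  contigs <- setNames(
    substring(seq_by_genome[truth$genome_id], truth$start, truth$end),
    truth$contig_id
  )
  list(contigs = contigs, truth = truth)
}

#' Assign per-sample community abundances
#'
#' The single target genome is pinned at `target_abundance` in every bulk
#' sample; the remainder is shared among non-targets with log-normal base
#' abundances and mild per-sample log-normal fluctuation, giving each genome
#' a distinctive differential-coverage profile.
#'
#' @param genomes Tibble from [simulate_genomes()].
#' @param n_samples Number of bulk samples.
#' @param target_abundance Target's relative abundance per sample (fraction).
#' @param target_id Genome id of the rare target; defaults to the first.
#' @param sample_sd Log-sd of the per-sample fluctuation of non-targets.
#' @param seed Integer seed.
#' @return Tibble `genome_id` x `sample` x `abundance`; abundances sum to 1
#'   within each sample.
#' @export
simulate_abundances <- function(genomes, n_samples = 3,
                                target_abundance = 0.01,
                                target_id = genomes$genome_id[1],
                                sample_sd = 0.6, seed = 1) {
  stopifnot(target_id %in% genomes$genome_id)
  if (target_abundance < 0 || target_abundance >= 1) {
    abort("`target_abundance` must be in [0, 1).")
  }
  others <- setdiff(genomes$genome_id, target_id)
  with_seed(seed, {
    base <- exp(rnorm(length(others), sd = 1))
    ab <- lapply(seq_len(n_samples), function(s) {
      w <- base * exp(rnorm(length(others), sd = sample_sd))
      w <- w / sum(w) * (1 - target_abundance)
      tibble(genome_id = c(target_id, others),
             sample = sprintf("MFS%d", s),
             abundance = c(target_abundance, w))
    })
  })
  bind_rows(ab)
}

#' Simulate per-contig per-sample coverage
#'
#' Expected depth of every contig of genome g in sample s is
#' `abundance(g, s) * total_depth * n_genomes` (a community of n equally
#' abundant genomes at `total_depth` would put each at `total_depth` fold).
#' The observed depth is noisy at the read level: the number of reads
#' starting on the contig is Poisson (or negative-binomial) with mean
#' `expected_depth * length / read_length`, and depth is reads *
#' read_length / length — so longer contigs have proportionally steadier
#' depth estimates, as in real mappings.
#'
#' @param truth Contig provenance tibble from [fragment_genomes()].
#' @param abundances Tibble from [simulate_abundances()].
#' @param total_depth Community-wide depth scale (fold, > 0).
#' @param noise `"poisson"` or `"nbinom"`.
#' @param nb_size Negative-binomial size (dispersion) when `noise = "nbinom"`.
#' @param read_length Read length (bp) controlling depth granularity.
#' @param seed Integer seed.
#' @return Tibble `contig` plus one numeric column per sample.
#' @export
simulate_coverage <- function(truth, abundances, total_depth = 40,
                              noise = c("poisson", "nbinom"), nb_size = 20,
                              read_length = 100, seed = 1) {
  noise <- match.arg(noise)
  if (total_depth <= 0) abort("`total_depth` must be > 0.")
  n_genomes <- length(unique(abundances$genome_id))
  samples <- unique(abundances$sample)
  ab <- tidyr::pivot_wider(abundances, names_from = "sample",
                           values_from = "abundance")
  ab_mat <- as.matrix(ab[, samples, drop = FALSE])
  rownames(ab_mat) <- ab$genome_id
  mu <- ab_mat[truth$genome_id, , drop = FALSE] * total_depth * n_genomes
  len <- truth$end - truth$start + 1
  mu_reads <- mu * len / read_length
  with_seed(seed, {
    reads <- switch(noise,
      poisson = matrix(rpois(length(mu_reads), lambda = mu_reads),
                       nrow = nrow(mu_reads)),
      nbinom = matrix(rnbinom(length(mu_reads), mu = mu_reads,
                              size = nb_size),
                      nrow = nrow(mu_reads))
    )
  })
  obs <- reads * read_length / len
  obs[mu == 0] <- 0
  out <- as_tibble(as.data.frame(obs))
  names(out) <- samples
  dplyr::bind_cols(tibble(contig = truth$contig_id), out)
}

#' Specify a sorted mini-metagenome well
#'
#' @param well_id Well name.
#' @param n_cells Cells sorted into the well, in \[10, 500\].
#' @param target_enrichment Probability a sorted cell is the target.
#' @param mda_sigma Log-normal dispersion of per-contig MDA amplification bias.
#' @return One-row tibble.
#' @export
well_spec <- function(well_id, n_cells, target_enrichment = 0.8,
                      mda_sigma = 1.5) {
  if (n_cells < 10 || n_cells > 500) abort("`n_cells` must be in [10, 500].")
  if (target_enrichment < 0 || target_enrichment > 1) {
    abort("`target_enrichment` must be in [0, 1].")
  }
  if (mda_sigma < 0) abort("`mda_sigma` must be >= 0.")
  tibble(well_id = well_id, n_cells = as.integer(n_cells),
         target_enrichment = target_enrichment, mda_sigma = mda_sigma)
}

#' Simulate sorted-well (mini-metagenome) coverage
#'
#' Each cell in a well is the target with probability `target_enrichment`,
#' otherwise a genome drawn proportionally to its mean bulk abundance. A
#' sampled genome contributes depth proportional to its cell count times
#' `depth_per_cell`, multiplied per contig by a log-normal MDA bias
#' `exp(N(0, mda_sigma^2))` — the extreme coverage unevenness of
#' amplified sorted-cell pools. Contigs of unsampled genomes get coverage 0.
#'
#' @param truth Contig provenance tibble from [fragment_genomes()].
#' @param abundances Tibble from [simulate_abundances()].
#' @param wells Tibble of [well_spec()] rows.
#' @param target_id Target genome id.
#' @param depth_per_cell Fold coverage contributed per sorted cell.
#' @param seed Integer seed.
#' @return Tibble `contig` plus one column per well, with attributes
#'   `enriched` (named logical: did the well receive >= 1 target cell, the
#'   in-silico analog of the PCR screen) and `cells` (well x genome counts).
#' @export
simulate_wells <- function(truth, abundances, wells, target_id,
                           depth_per_cell = 1, seed = 1) {
  stopifnot(nrow(wells) >= 1L)
  genome_ids <- unique(abundances$genome_id)
  mean_ab <- summarise(group_by(abundances, .data$genome_id),
                       ab = mean(.data$abundance))
  bulk_p <- setNames(mean_ab$ab, mean_ab$genome_id)[genome_ids]
  others <- setdiff(genome_ids, target_id)
  with_seed(seed, {
    cols <- list(); enriched <- logical(nrow(wells)); cell_tabs <- list()
    for (i in seq_len(nrow(wells))) {
      w <- wells[i, ]
      is_target <- runif(w$n_cells) < w$target_enrichment
      if (length(others) == 0L) is_target[] <- TRUE
      n_other <- sum(!is_target)
      drawn <- c(rep(target_id, sum(is_target)),
                 if (n_other > 0) sample(others, n_other, replace = TRUE,
                                         prob = bulk_p[others] / sum(bulk_p[others])))
      counts <- table(factor(drawn, levels = genome_ids))
      cell_tabs[[i]] <- tibble(well_id = w$well_id, genome_id = genome_ids,
                               cells = as.integer(counts))
      enriched[i] <- counts[[target_id]] > 0
      base <- as.numeric(counts)[match(truth$genome_id, genome_ids)] *
        depth_per_cell
      bias <- exp(rnorm(nrow(truth), sd = w$mda_sigma))
      cov <- base * bias
      cov[base == 0] <- 0
      cols[[w$well_id]] <- cov
    }
  })
  out <- dplyr::bind_cols(tibble(contig = truth$contig_id), as_tibble(cols))
  structure(out,
            enriched = setNames(enriched, wells$well_id),
            cells = bind_rows(cell_tabs))
}

#' Plant single-copy markers on contigs
#'
#' Every genome receives each of `n_markers` universal single-copy markers
#' exactly once, on one of its contigs chosen uniformly at random — the
#' ground truth behind the completeness/contamination statistics.
#'
#' @param truth Contig provenance tibble from [fragment_genomes()].
#' @param n_markers Number of markers per genome (>= 1).
#' @param seed Integer seed.
#' @return Tibble `contig`, `marker_id`, `copies` (all 1).
#' @export
plant_markers <- function(truth, n_markers = 100, seed = 1) {
  if (n_markers < 1) abort("`n_markers` must be >= 1.")
  marker_ids <- sprintf("marker_%03d", seq_len(n_markers))
  with_seed(seed, {
    hits <- lapply(split(truth$contig_id, truth$genome_id), function(ctgs) {
      tibble(contig = sample(ctgs, n_markers, replace = TRUE),
             marker_id = marker_ids, copies = 1L)
    })
  })
  arrange(bind_rows(hits), .data$marker_id, .data$contig)
}

#' Simulate a 16S rRNA alignment with a target-only signature insert
#'
#' Evolves `n_taxa` sequences from a common ancestor at a configurable
#' substitution divergence, then gives the first (target) taxon an
#' `insert_len`-bp insertion: in the returned alignment those columns are
#' residues in the target and gaps in every non-target — the signature
#' exploitable for clade-specific primers and probes.
#'
#' @param n_taxa Number of taxa (>= 3); the first is the target.
#' @param seq_length Unaligned sequence length before insertion.
#' @param insert_len Insert length in bp (0 = no insert).
#' @param divergence Per-site substitution probability from the ancestor.
#' @param seed Integer seed.
#' @return List with `alignment` (named character, equal lengths, gaps as
#'   `-`), `sequences` (unaligned), `target_id`, `insert_start` (1-based
#'   alignment column or `NA`), `insert_len`.
#' @export
simulate_16s <- function(n_taxa = 8, seq_length = 1500, insert_len = 14,
                         divergence = 0.05, seed = 1) {
  if (n_taxa < 3) abort("`n_taxa` must be >= 3.")
  if (insert_len < 0) abort("`insert_len` must be >= 0.")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    anc <- sample(bases, seq_length, replace = TRUE)
    taxa <- c("target_16S", sprintf("relative_%02d", seq_len(n_taxa - 1L)))
    seqs <- lapply(seq_len(n_taxa), function(i) {
      s <- anc
      hit <- runif(seq_length) < divergence
      if (any(hit)) {
        # substitute to a uniformly chosen different base
        s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
      s
    })
    names(seqs) <- taxa
    ins_point <- as.integer(round(seq_length * 0.35))
    ins <- if (insert_len > 0) sample(bases, insert_len, replace = TRUE)
      else character(0)
  })
  aln <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    mid <- if (i == 1L) ins else rep("-", insert_len)
    paste(c(s[seq_len(ins_point)], mid, s[(ins_point + 1L):seq_length]),
          collapse = "")
  }, character(1))
  names(aln) <- names(seqs)
  unaln <- vapply(aln, function(s) gsub("-", "", s), character(1))
  list(alignment = aln, sequences = unaln, target_id = names(aln)[1L],
       insert_start = if (insert_len > 0) ins_point + 1L else NA_integer_,
       insert_len = insert_len)
}

#' Simulate toy proteomes with a shared conserved core
#'
#' Builds a family of proteomes in which a configurable fraction of proteins
#' descend from shared ancestors (diverged by point substitutions) and the
#' rest are random, for exercising conserved-protein statistics at desk
#' scale.
#'
#' @param n_proteomes Number of proteomes.
#' @param n_proteins Proteins per proteome.
#' @param shared_frac Fraction of proteins with shared ancestry.
#' @param protein_len Mean protein length (aa).
#' @param divergence Per-residue substitution probability from the ancestor.
#' @param seed Integer seed.
#' @return Named list of named character vectors of amino-acid sequences.
#' @export
simulate_proteomes <- function(n_proteomes = 3, n_proteins = 30,
                               shared_frac = 0.7, protein_len = 120,
                               divergence = 0.1, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_shared <- round(n_proteins * shared_frac)
  with_seed(seed, {
    lens <- pmax(40L, as.integer(round(rnorm(n_proteins, protein_len, 20))))
    shared_lens <- if (n_shared > 0) lens[seq_len(n_shared)] else integer(0)
    private_lens <- if (n_shared < n_proteins) {
      lens[(n_shared + 1L):n_proteins]
    } else integer(0)
    anc <- lapply(shared_lens, function(L) sample(aa, L, replace = TRUE))
    out <- lapply(seq_len(n_proteomes), function(p) {
      prots <- c(
        lapply(anc, function(s) {
          hit <- runif(length(s)) < divergence
          s[hit] <- sample(aa, sum(hit), replace = TRUE)
          paste(s, collapse = "")
        }),
        lapply(private_lens, function(L)
          paste(sample(aa, L, replace = TRUE), collapse = ""))
      )
      setNames(unlist(prots), sprintf("p%d_prot%03d", p, seq_len(n_proteins)))
    })
    names(out) <- sprintf("proteome_%d", seq_len(n_proteomes))
  })
  out
}

#' Generate the full synthetic study scenario
#'
#' One call produces every input the recovery pipeline consumes, with the
#' statistical structure of the study design: a diverse bulk community with
#' one rare target lineage, several bulk samples with differential coverage,
#' sorted wells of 10-500 cells enriched in the target with strong MDA bias,
#' planted single-copy markers, and a 16S alignment carrying a target-only
#' signature insert.
#'
#' @param config Scenario configuration from [default_scenario()] (fields may
#'   be overridden).
#' @param seed Integer seed governing every random draw.
#' @return List of class `rm_community`: `genomes`, `contigs`, `truth`
#'   (contig map + abundances + markers + insert coordinates), `coverage`,
#'   `wells`, `markers`, `rrna`, `target_id`.
#' @export
simulate_community <- function(config = default_scenario(), seed = 1) {
  cfg <- config
  genomes <- simulate_genomes(cfg$n_genomes, cfg$mean_genome_length,
                              seed = seed)
  target_id <- genomes$genome_id[1L]
  frag <- fragment_genomes(genomes, cfg$min_contig_length,
                           cfg$max_contig_length, seed = seed + 1L)
  ab <- simulate_abundances(genomes, cfg$n_samples, cfg$target_abundance,
                            target_id = target_id, seed = seed + 2L)
  cov <- simulate_coverage(frag$truth, ab, cfg$total_depth, cfg$noise,
                           seed = seed + 3L)
  wells <- do.call(rbind, lapply(seq_len(cfg$n_wells), function(i)
    well_spec(sprintf("well_%d", i), cfg$well_cells[i],
              cfg$target_enrichment, cfg$mda_sigma)))
  well_cov <- simulate_wells(frag$truth, ab, wells, target_id,
                             seed = seed + 4L)
  markers <- plant_markers(frag$truth, cfg$n_markers, seed = seed + 5L)
  rrna <- simulate_16s(cfg$n_16s_taxa, insert_len = cfg$insert_length,
                       divergence = cfg$divergence_16s, seed = seed + 6L)
  structure(list(
    genomes = genomes[, c("genome_id", "length", "gc_target")],
    contigs = frag$contigs,
    truth = list(contig_map = frag$truth, abundances = ab, markers = markers,
                 insert = list(genome = target_id,
                               start = rrna$insert_start,
                               length = rrna$insert_len)),
    coverage = cov, wells = well_cov, markers = markers, rrna = rrna,
    target_id = target_id, config = cfg, seed = seed
  ), class = "rm_community")
}

#' Default synthetic scenario
#'
#' The study conditions exercised throughout the package: 25 genomes with the
#' rare target at 1% in each of 3 bulk samples, 4 sorted wells of 10-500
#' cells at 0.8 target enrichment under strong MDA bias (sigma 1.5), 100
#' planted single-copy markers, and a 14-bp target-only 16S insert.
#'
#' @param ... Named overrides of individual fields.
#' @return Named list of scenario parameters.
#' @export
default_scenario <- function(...) {
  cfg <- list(
    n_genomes = 25L,
    mean_genome_length = 3e5,
    min_contig_length = 1500L,
    max_contig_length = 20000L,
    n_samples = 3L,
    target_abundance = 0.01,
    total_depth = 40,
    noise = "poisson",
    n_wells = 4L,
    well_cells = c(50L, 120L, 300L, 480L),
    target_enrichment = 0.8,
    mda_sigma = 1.5,
    n_markers = 100L,
    insert_length = 14L,
    n_16s_taxa = 8L,
    divergence_16s = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) abort(paste0("Unknown scenario field: ", bad[1L]))
  cfg[names(over)] <- over
  cfg
}

#' @export
print.rm_community <- function(x, ...) {
  cat("<rm_community> ", nrow(x$genomes), " genomes, ",
      length(x$contigs), " contigs, ",
      ncol(x$coverage) - 1L, " bulk sample(s), ",
      ncol(x$wells) - 1L, " well(s); target ", x$target_id, "\n", sep = "")
  invisible(x)
}
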