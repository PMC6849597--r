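test_that("genome simulation is deterministic and hits its GC targets", {
  expect_equal(nrow(simulate_genomes(0)), 0L)
  g1 <- simulate_genomes(3, 6e4, seed = 7)
  g2 <- simulate_genomes(3, 6e4, seed = 7)
  expect_identical(g1, g2)
  expect_true(all(grepl("^[ACGT]+$", g1$sequence)))
  realized <- vapply(g1$sequence, gc_content, numeric(1), USE.NAMES = FALSE)
  expect_true(all(abs(realized - g1$gc_target) <= 0.02))
  expect_error(simulate_genomes(-1), "n_genomes")
  expect_error(simulate_genomes(2, mean_length = 1e4), "50000")
})

test_that("high-GC genomes land in the requested band by direct counting", {
  g <- simulate_genomes(1, 1e5, seed = 3, gc_range = c(0.60, 0.60))
  bases <- table(strsplit(g$sequence, "")[[1]])
  gc <- (bases[["G"]] + bases[["C"]]) / sum(bases)
  expect_gte(gc, 0.58)
  expect_lte(gc, 0.62)
})

test_that("fragmentation tiles genomes exactly and conserves sequence", {
  g <- simulate_genomes(1, 1e5, seed = 5)
  g$length <- 10000L
  g$sequence <- substr(g$sequence, 1, 10000)
  fr <- fragment_genomes(g, 2500, 2500, seed = 1)
  expect_equal(length(fr$contigs), 4L)
  expect_true(all(nchar(fr$contigs) == 2500))
  # conservation and order: concatenation reproduces a genome substring
  expect_lte(sum(nchar(fr$contigs)), g$length)
  joined <- paste(fr$contigs[order(fr$truth$start)], collapse = "")
  expect_true(grepl(joined, g$sequence, fixed = TRUE))
  expect_error(fragment_genomes(g, 5000, 2500), "min_len")
  expect_error(fragment_genomes(g, 500, 2500), "1000")
})

test_that("every contig maps to exactly one genome and lengths conserve", {
  comm <- paper_community()
  cm <- comm$truth$contig_map
  expect_equal(anyDuplicated(cm$contig_id), 0L)
  per_genome <- tapply(cm$end - cm$start + 1, cm$genome_id, sum)
  glen <- setNames(comm$genomes$length, comm$genomes$genome_id)
  expect_true(all(per_genome <= glen[names(per_genome)]))
})

test_that("abundances sum to one per sample with the target pinned", {
  g <- simulate_genomes(4, 6e4, seed = 2)
  ab <- simulate_abundances(g, 3, 0.01, seed = 9)
  sums <- tapply(ab$abundance, ab$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  tgt <- ab[ab$genome_id == g$genome_id[1], ]
  expect_true(all(tgt$abundance == 0.01))
})

test_that("coverage respects zero abundance and matches its expectation", {
  g <- simulate_genomes(2, 6e4, seed = 4)
  fr <- fragment_genomes(g, 2000, 2000, seed = 1)
  ab <- tibble::tibble(
    genome_id = rep(g$genome_id, each = 2),
    sample = rep(c("s1", "s2"), 2),
    abundance = c(0, 0.5, 1, 0.5)
  )
  cov <- simulate_coverage(fr$truth, ab, total_depth = 10, seed = 1)
  g1 <- fr$truth$contig_id[fr$truth$genome_id == g$genome_id[1]]
  expect_true(all(cov$s1[cov$contig %in% g1] == 0))
  expect_error(simulate_coverage(fr$truth, ab, total_depth = 0), "total_depth")

  # Monte-Carlo mean within 3 standard errors of the closed form
  one_contig <- fr$truth[fr$truth$genome_id == g$genome_id[2], ][1, ]
  ab_s1 <- ab[ab$sample == "s1", ]
  mu <- 1 * 10 * 2                       # abundance * depth * n_genomes
  len <- one_contig$end - one_contig$start + 1
  draws <- vapply(1:1000, function(s) {
    simulate_coverage(one_contig, ab_s1, total_depth = 10, seed = s)$s1
  }, numeric(1))
  se <- sqrt(mu * 100 / len) / sqrt(1000)  # var(depth) = mu * read_len / len
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("well simulation honours enrichment, bias and absence", {
  g <- simulate_genomes(1, 6e4, seed = 6)
  fr <- fragment_genomes(g, 2000, 4000, seed = 1)
  ab <- tibble::tibble(genome_id = g$genome_id, sample = "s1", abundance = 1)
  w <- well_spec("w1", 50, target_enrichment = 1, mda_sigma = 0)
  wc <- simulate_wells(fr$truth, ab, w, g$genome_id[1], seed = 1)
  expect_true(all(wc$w1 > 0))                 # one-genome community: all hit
  expect_true(all(wc$w1 == wc$w1[1]))         # sigma 0: flat depth
  expect_error(well_spec("bad", 5), "n_cells")
  expect_error(well_spec("bad", 50, target_enrichment = 1.2), "enrichment")

  # contigs of unsampled genomes have zero coverage
  g3 <- simulate_genomes(3, 6e4, seed = 8)
  fr3 <- fragment_genomes(g3, 2000, 4000, seed = 2)
  ab3 <- simulate_abundances(g3, 1, 0.3, seed = 3)
  w3 <- well_spec("w1", 10, target_enrichment = 1, mda_sigma = 1)
  wc3 <- simulate_wells(fr3$truth, ab3, w3, g3$genome_id[1], seed = 4)
  non_target <- fr3$truth$contig_id[fr3$truth$genome_id != g3$genome_id[1]]
  expect_true(all(wc3$w1[wc3$contig %in% non_target] == 0))
})

test_that("four wells at 0.8 enrichment carry the target with the exact binomial odds", {
  # P(target sampled in >= 3 of 4 wells) where each well of >= 10 cells
  # misses the target with probability (1 - 0.8)^10 at most
  p_miss <- (1 - 0.8)^10
  p_present <- 1 - p_miss
  p_ge3 <- binom_tail_oracle(3, 4, p_present)
  expect_gte(p_ge3, 0.97)
  comm <- paper_community()
  enriched <- attr(comm$wells, "enriched")
  tgt_contigs <- comm$truth$contig_map$contig_id[
    comm$truth$contig_map$genome_id == comm$target_id]
  pres <- as.matrix(comm$wells[comm$wells$contig %in% tgt_contigs,
                               names(enriched)]) >= 1
  expect_gte(sum(colSums(pres) > 0), 3)
})

test_that("marker planting gives every genome one copy of each marker", {
  comm <- paper_community()
  mk <- comm$markers
  cm <- comm$truth$contig_map
  mk$genome <- cm$genome_id[match(mk$contig, cm$contig_id)]
  per <- tapply(mk$copies, list(mk$genome, mk$marker_id), sum)
  expect_true(all(per == 1))
  expect_error(plant_markers(cm, 0), "n_markers")
})

test_that("16S fixture carries exactly the configured target-only insert", {
  rr <- simulate_16s(6, 800, insert_len = 14, divergence = 0.04, seed = 3)
  ins <- find_inserts(rr$alignment, rr$target_id)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$length, 14L)
  rr0 <- simulate_16s(6, 800, insert_len = 0, divergence = 0.04, seed = 3)
  expect_equal(nrow(find_inserts(rr0$alignment, rr0$target_id)), 0L)
  # zero divergence: identical sequences away from the insert
  rrid <- simulate_16s(3, 500, insert_len = 0, divergence = 0, seed = 5)
  expect_equal(p_distance(rrid$alignment[[1]], rrid$alignment[[2]]), 0)
  expect_error(simulate_16s(2, 500), "n_taxa")
})

test_that("simulator operations are pure functions of their seed", {
  a <- simulate_community(default_scenario(n_genomes = 3L,
                                           mean_genome_length = 6e4,
                                           well_cells = c(20L, 30L, 40L, 50L)),
                          seed = 42)
  b <- simulate_community(default_scenario(n_genomes = 3L,
                                           mean_genome_length = 6e4,
                                           well_cells = c(20L, 30L, 40L, 50L)),
                          seed = 42)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$coverage, b$coverage)
  expect_identical(as.data.frame(a$wells), as.data.frame(b$wells))
  expect_identical(a$rrna, b$rrna)
})
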