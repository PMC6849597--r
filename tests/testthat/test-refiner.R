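ref_feats <- function(covs) {
  set.seed(17)
  seqs <- setNames(vapply(seq_len(nrow(covs)), function(i)
    random_dna(3000), character(1)), covs$contig)
  build_features(seqs, covs)
}

test_that("coverage compatibility flags log2 deviations beyond tau", {
  cov <- tibble::tibble(contig = sprintf("c%d", 1:4),
                        s1 = c(10, 10, 10, 10), s2 = c(5, 5, 5, 5))
  f <- ref_feats(cov)
  cc <- coverage_compatibility("c1", c("c1", "c2", "c3", "c4"), f)
  expect_true(cc$compatible)
  expect_equal(unname(cc$deviation), c(0, 0))

  # 8x the bin median in every sample: |log2 8| = 3 > 1 everywhere
  cov2 <- rbind(cov, tibble::tibble(contig = "hot", s1 = 80, s2 = 40))
  f2 <- ref_feats(cov2)
  cc2 <- coverage_compatibility("hot", c("c1", "c2", "c3", "c4"), f2,
                                tau = 1, s_max = 0)
  expect_false(cc2$compatible)
  expect_true(all(cc2$deviation > 1))

  expect_warning(cc3 <- coverage_compatibility("c1", c("c1", "c2"), f),
                 "fewer than 3")
  expect_true(cc3$compatible)
  expect_error(coverage_compatibility("nope", cov$contig, f), "nope")
})

test_that("well enrichment equals the exact binomial tail", {
  # 10 contigs x 4 enriched wells; only c1 is present, in all 4 wells,
  # so the background rate is exactly 4/40 = 0.1
  wells <- tibble::tibble(contig = sprintf("c%d", 1:10))
  for (w in sprintf("w%d", 1:4)) wells[[w]] <- c(5, rep(0, 9))
  attr(wells, "enriched") <- setNames(rep(TRUE, 4), sprintf("w%d", 1:4))
  expect_equal(well_enrichment("c1", wells), 4, tolerance = 1e-9)
  expect_equal(well_enrichment("c2", wells), 0)  # k = 0 -> P = 1

  # saturated background: score 0 regardless of k
  sat <- tibble::tibble(contig = c("a", "b"), w1 = c(5, 5), w2 = c(5, 5))
  attr(sat, "enriched") <- c(w1 = TRUE, w2 = TRUE)
  expect_equal(well_enrichment("a", sat), 0)

  none <- tibble::tibble(contig = "a", w1 = 5)
  attr(none, "enriched") <- c(w1 = FALSE)
  expect_error(well_enrichment("a", none), "enriched")
})

test_that("well enrichment is monotone in presence count and matches the oracle", {
  for (k in 0:4) {
    wells <- tibble::tibble(contig = sprintf("c%d", 1:10))
    for (i in 1:4) {
      wells[[paste0("w", i)]] <- c(if (i <= k) 5 else 0, rep(0, 8), 5)
    }
    attr(wells, "enriched") <- setNames(rep(TRUE, 4), sprintf("w%d", 1:4))
    pres <- as.matrix(wells[, -1]) >= 1
    p0 <- mean(pres)
    expected <- -log10(binom_tail_oracle(k, 4, p0))
    expect_equal(well_enrichment("c1", wells), max(0, expected),
                 tolerance = 1e-9)
  }
})

test_that("taxon consistency majorities are length-weighted with stated policies", {
  cov <- tibble::tibble(contig = sprintf("c%d", 1:10), s1 = rep(5, 10))
  f <- ref_feats(cov)
  taxa <- tibble::tibble(contig_id = sprintf("c%d", 1:10),
                         family = c(rep("Rhizobiales", 9), "Actinobacteria"))
  tc <- taxon_consistency(cov$contig, taxa, "family", f)
  expect_equal(tc$majority, "Rhizobiales")
  expect_equal(tc$outliers, "c10")

  same <- taxon_consistency(cov$contig[1:9], taxa, "family", f)
  expect_length(same$outliers, 0L)

  unl <- tibble::tibble(contig_id = cov$contig,
                        family = rep(NA_character_, 10))
  tc2 <- taxon_consistency(cov$contig, unl, "family", f)
  expect_equal(tc2$majority, "unclassified")
  expect_length(tc2$outliers, 0L)
  expect_error(taxon_consistency(character(0), taxa, "family", f), "Empty")
})

test_that("refine_bin removes exactly the planted discordant contig and is idempotent", {
  cov <- tibble::tibble(contig = sprintf("c%d", 1:6),
                        s1 = c(10, 11, 9, 10, 10, 95),
                        s2 = c(20, 19, 21, 20, 20, 2))
  f <- ref_feats(cov)
  rf <- refine_bin(cov$contig, f)
  expect_setequal(rf$contig_ids, sprintf("c%d", 1:5))
  expect_equal(rf$report$contig_id, "c6")
  expect_equal(rf$report$reason, "coverage_incompatible")

  # clean bin: unchanged, empty report
  rf2 <- refine_bin(sprintf("c%d", 1:5), f)
  expect_setequal(rf2$contig_ids, sprintf("c%d", 1:5))
  expect_equal(nrow(rf2$report), 0L)

  # idempotence
  rf3 <- refine_bin(rf$contig_ids, f)
  expect_setequal(rf3$contig_ids, rf$contig_ids)
  expect_equal(nrow(rf3$report), 0L)
})

test_that("refinement never increases marker contamination (random perturbed bins)", {
  comm <- paper_community()
  f <- paper_features()
  cm <- comm$truth$contig_map
  marker_set <- sort(unique(comm$markers$marker_id))
  genomes <- unique(cm$genome_id)
  set.seed(404)
  for (i in 1:50) {
    g <- sample(genomes, 1)
    own <- cm$contig_id[cm$genome_id == g]
    foreign <- sample(cm$contig_id[cm$genome_id != g], sample(1:4, 1))
    dirty <- c(own, foreign)
    before <- completeness_contamination(dirty, comm$markers,
                                         marker_set)$contamination
    rf <- suppressWarnings(refine_bin(dirty, f, wells = comm$wells))
    after <- completeness_contamination(rf$contig_ids, comm$markers,
                                        marker_set)$contamination
    expect_lte(after, before + 1e-9)
  }
})

test_that("unbinned contigs associate to the coverage-compatible bin", {
  comm <- paper_community()
  f <- paper_features()
  bins <- bin_contigs(f)
  sc <- score_recovery(bins, comm$truth$contig_map, f, comm$target_id)
  target_bin <- sc$target_bin
  # remove one target contig and let association bring it home
  members <- bins$contig_id[bins$bin_id == target_bin]
  probe <- members[which.min(f$length[match(members, f$contig_id)])]
  bins2 <- bins[bins$contig_id != probe, ]
  hit <- associate_unbinned(probe, bins2, f, wells = comm$wells)
  expect_equal(hit$bin_id, target_bin)

  # a contig compatible with nothing returns none
  cov <- tibble::tibble(contig = c(sprintf("b%d", 1:3), "lonely"),
                        s1 = c(10, 10, 10, 4000), s2 = c(10, 10, 10, 4000))
  f2 <- ref_feats(cov)
  fake_bins <- tibble::tibble(contig_id = sprintf("b%d", 1:3),
                              bin_id = "bin_01", provenance = "clustered")
  miss <- associate_unbinned("lonely", fake_bins, f2)
  expect_true(is.na(miss$bin_id))

  # tie between two equally compatible bins breaks by bin id
  cov3 <- tibble::tibble(contig = c(sprintf("x%d", 1:3), sprintf("y%d", 1:3),
                                    "probe"),
                         s1 = c(rep(10, 6), 10), s2 = c(rep(10, 6), 10))
  f3 <- ref_feats(cov3)
  two_bins <- tibble::tibble(
    contig_id = c(sprintf("x%d", 1:3), sprintf("y%d", 1:3)),
    bin_id = rep(c("bin_b", "bin_a"), each = 3),
    provenance = "clustered")
  tie <- associate_unbinned("probe", two_bins, f3)
  expect_equal(tie$bin_id, "bin_a")
})

test_that("refining all bins does not lower target-bin precision", {
  comm <- paper_community()
  f <- paper_features()
  bins <- bin_contigs(f)
  before <- score_recovery(bins, comm$truth$contig_map, f, comm$target_id)
  rf <- refine_bins(bins, f, wells = comm$wells)
  after <- score_recovery(rf$bins, comm$truth$contig_map, f, comm$target_id)
  expect_gte(after$target_precision, before$target_precision - 1e-9)
})
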