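test_that("align_pair matches the independent DP oracle on toy pairs", {
  # arbitrary random pairs: optimal local score must match the oracle
  # (co-optimal alignments can differ in identity, so identity is checked
  # on the unambiguous pairs below)
  set.seed(55)
  for (i in 1:25) {
    q <- random_protein(sample(20:60, 1))
    s <- random_protein(sample(20:60, 1))
    got <- align_pair(q, s)
    want <- sw_oracle(q, s)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
  # pairs over {W, F, Y} score positively for every residue pair, so the
  # unique optimum is the full-length ungapped alignment and identity is
  # the exact mismatch count
  set.seed(56)
  wfy <- c("W", "F", "Y")
  for (i in 1:25) {
    n <- sample(25:60, 1)
    v <- sample(wfy, n, replace = TRUE)
    w <- v
    hit <- runif(n) < 0.2
    w[hit] <- vapply(w[hit], function(x) sample(setdiff(wfy, x), 1),
                     character(1))
    q <- paste(v, collapse = ""); s <- paste(w, collapse = "")
    got <- align_pair(q, s)
    want <- sw_oracle(q, s)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$identity_pct, want$identity_pct, tolerance = 1e-9)
    expect_equal(got$identity_pct, 100 * mean(v == w), tolerance = 1e-9)
    expect_equal(got$aligned_fraction, 1)
  }
})

test_that("align_pair handles identity and degenerate inputs", {
  p <- random_protein(100, seed = 9)
  a <- align_pair(p, p)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$aligned_fraction, 1)
  expect_lt(a$evalue, 1e-5)
  expect_error(align_pair("", p), "protein")
  expect_error(align_pair("MKV1", p), "alphabet")
})

test_that("conserved-protein counting applies all three thresholds", {
  set.seed(66)
  core <- random_protein(60)
  p1 <- c(A = core, B = random_protein(50))
  p2 <- c(Aprime = core, C = random_protein(40))
  cc <- count_conserved(p1, p2)
  expect_equal(cc$C1, 1L)
  expect_equal(cc$C2, 1L)
  expect_equal(cc$T1, 2L)
  expect_equal(cc$T2, 2L)

  # identical proteomes: everything conserved
  idp <- setNames(vapply(1:5, function(i) random_protein(80, seed = i),
                         character(1)), paste0("p", 1:5))
  ci <- count_conserved(idp, idp)
  expect_equal(ci$C1, 5L)
  expect_equal(ci$C2, 5L)

  # unrelated proteomes: nothing conserved
  u1 <- setNames(vapply(11:14, function(i) random_protein(70, seed = i),
                        character(1)), paste0("u", 1:4))
  u2 <- setNames(vapply(21:24, function(i) random_protein(70, seed = i),
                        character(1)), paste0("v", 1:4))
  cu <- count_conserved(u1, u2)
  expect_equal(cu$C1, 0L)
  expect_equal(cu$C2, 0L)

  # short proteins are skipped with a warning
  expect_warning(count_conserved(c(p1, tiny = "MKV"), p2), "skipped")
})

test_that("pocp value, symmetry and self-identity follow the formula", {
  set.seed(77)
  core <- random_protein(60)
  p1 <- c(A = core, B = random_protein(50))
  p2 <- c(Aprime = core, C = random_protein(40))
  r <- pocp(p1, p2)
  expect_equal(r$value, 50)              # (1 + 1) / (2 + 2) * 100
  expect_equal(r$value,
               100 * (r$C1 + r$C2) / (r$T1 + r$T2))
  expect_equal(pocp(p2, p1)$value, r$value)

  idp <- setNames(vapply(1:4, function(i) random_protein(90, seed = i),
                         character(1)), paste0("p", 1:4))
  expect_identical(pocp(idp, idp)$value, 100)

  u1 <- setNames(vapply(31:34, function(i) random_protein(70, seed = i),
                        character(1)), paste0("u", 1:4))
  u2 <- setNames(vapply(41:44, function(i) random_protein(70, seed = i),
                        character(1)), paste0("v", 1:4))
  expect_equal(pocp(u1, u2)$value, 0)
  expect_s3_class(tidy(r), "tbl_df")
})

test_that("removing a non-conserved protein raises POCP, adding one lowers it", {
  set.seed(101)
  core1 <- random_protein(60); core2 <- random_protein(55)
  p1 <- c(A = core1, B = core2, junk = random_protein(50))
  p2 <- c(A2 = core1, B2 = core2)
  with_junk <- pocp(p1, p2)$value
  without <- pocp(p1[c("A", "B")], p2)$value
  expect_gte(without, with_junk)
  more_junk <- pocp(c(p1, junk2 = random_protein(45)), p2)$value
  expect_lte(more_junk, with_junk)
})

test_that("genus grouping is complete-linkage over the cutoff", {
  all60 <- matrix(60, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(all60) <- 100
  g <- genus_clusters(all60)
  expect_equal(length(unique(g$group)), 1L)
  expect_false(any(g$singleton))

  # a target below 44 to everything is a singleton novel-genus candidate
  m <- matrix(60, 4, 4,
              dimnames = list(c("tgt", "r1", "r2", "r3"),
                              c("tgt", "r1", "r2", "r3")))
  m["tgt", ] <- m[, "tgt"] <- 44
  diag(m) <- 100
  g2 <- genus_clusters(m)
  expect_true(g2$singleton[g2$genome_id == "tgt"])
  expect_equal(length(unique(g2$group[g2$genome_id != "tgt"])), 1L)

  # chain A-B 55, B-C 55, A-C 45: no 3-clique; {A,B} wins lexicographically
  ch <- matrix(c(100, 55, 45, 55, 100, 55, 45, 55, 100), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  g3 <- genus_clusters(ch)
  expect_equal(g3$group[g3$genome_id == "A"], g3$group[g3$genome_id == "B"])
  expect_true(g3$singleton[g3$genome_id == "C"])

  asym <- all60; asym[1, 2] <- 61
  expect_error(genus_clusters(asym), "asymmetric")
})

test_that("simulated proteome family separates in from out of genus", {
  prots <- simulate_proteomes(3, n_proteins = 12, shared_frac = 0.75,
                              divergence = 0.08, seed = 5)
  m <- pocp_matrix(prots)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 100))
  offdiag <- m[upper.tri(m)]
  expect_true(all(offdiag > 50))   # same simulated genus: shared core
})
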