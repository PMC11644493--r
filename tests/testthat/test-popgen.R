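test_that("diversity matches the hand-computed four-haplotype example", {
  aln <- make_fixture("toy_pi")
  d <- diversity(aln, "pop1")
  expect_equal(d$S, 2L)
  expect_equal(d$pi, (7 / 6) / 10)          # all six pairs, ten sites
  expect_equal(d$theta_w, 2 / ((1 + 1 / 2 + 1 / 3) * 10))
  expect_equal(diversity(make_fixture("monomorphic"), "pop1")$pi, 0)
  expect_error(diversity(aln, "nope"), "sample-size error")
})

test_that("pi, S and theta_W equal brute-force all-pairs computation", {
  withr::local_seed(61)
  for (i in 1:12) {
    n <- sample(3:12, 1)
    L <- sample(30:200, 1)
    aln <- random_alignment(n, L, n_mut = sample(2:25, 1),
                            missing = sample(0:10, 1))
    d <- diversity(aln, "pop1")
    b <- brute_diversity(aln, "pop1")
    expect_equal(d$S, b$S)
    expect_equal(d$pi, b$pi)
    expect_equal(d$theta_w, b$theta_w)
    expect_equal(d$L_analyzed, b$L_analyzed)
  }
})

test_that("diversity is invariant to haplotype order and complementation", {
  withr::local_seed(67)
  aln <- random_alignment(8, 120, n_mut = 15, missing = 6)
  d0 <- diversity(aln, "pop1")
  perm <- sample(8)
  shuf <- pop_alignment(unname(alignment_sequences(aln))[perm],
                        sample_id = aln$sample_id[perm],
                        population = "pop1")
  comp <- pop_alignment(
    vapply(alignment_sequences(aln),
           function(s) chartr("ACGT", "TGCA", s), character(1),
           USE.NAMES = FALSE),
    sample_id = aln$sample_id, population = "pop1")
  for (alt in list(shuf, comp)) {
    d1 <- diversity(alt, "pop1")
    expect_equal(d1$pi, d0$pi)
    expect_equal(d1$theta_w, d0$theta_w)
  }
})

test_that("divergence counts per-site differences to the outgroup", {
  base <- paste(rep("A", 100), collapse = "")
  seq2 <- paste0(substr(base, 1, 99), "C")  # one difference
  seq3 <- paste0("G", substr(base, 2, 100))
  aln <- pop_alignment(c(seq2, seq3, base), c("i1", "i2", "og"),
                       c("pop1", "pop1", "outgroup"))
  expect_equal(divergence(aln, "pop1"), 0.01)
  same <- pop_alignment(c(base, base, base), c("i1", "i2", "og"),
                        c("pop1", "pop1", "outgroup"))
  expect_equal(divergence(same, "pop1"), 0)
  expect_gt(divergence(aln, "pop1", jukes_cantor = TRUE),
            divergence(aln, "pop1"))
  expect_error(divergence(aln, "pop1", outgroup_label = "missing"),
               "labeling error")
})

test_that("sliding windows count, zero out and localize correctly", {
  withr::local_seed(71)
  aln <- random_alignment(6, 25, n_mut = 4)
  sw <- sliding_pi(aln, "pop1", w = 21)
  expect_equal(nrow(sw), 5L)
  expect_equal(sw$window_start, 0:4)

  mono <- pop_alignment(rep(paste(rep("ACGT", 15), collapse = ""), 4))
  expect_true(all(sliding_pi(mono, "ingroup")$pi == 0))

  # single polymorphic column at 0-based position 30 of a 60-column locus
  anc <- sample(c("A", "C", "G", "T"), 60, TRUE)
  mat <- matrix(rep(anc, each = 4), 4)
  mat[1:2, 31] <- setdiff(c("A", "C", "G", "T"), anc[31])[1]
  poly <- pop_alignment(apply(mat, 1, paste, collapse = ""))
  sw2 <- sliding_pi(poly, "ingroup")
  nz <- sw2$window_start[sw2$pi > 0]
  expect_equal(nz, 10:30)
  expect_error(sliding_pi(poly, "ingroup", w = 100), "window error")
  # for L = w the single window equals whole-region pi
  one <- sliding_pi(aln, "pop1", w = 25)
  expect_equal(one$pi, diversity(aln, "pop1")$pi)
})

test_that("outgroup polarization assigns derived alleles and exclusions", {
  aln <- make_fixture("sweep_site")
  sfs <- polarize(aln, "pop1")
  expect_equal(sfs$n, 4L)
  expect_equal(unname(sfs$xi[3]), 1L)        # one site at derived count 3
  expect_equal(sfs$daf$daf, 0.75)
  expect_equal(sfs$unpolarized, 0L)

  # outgroup carrying a third allele leaves the site unpolarized
  aln2 <- pop_alignment(c("AAAA", "AAGA", "AAGA", "AACA"),
                        c("s1", "s2", "s3", "og"),
                        c(rep("pop1", 3), "outgroup"))
  sfs2 <- polarize(aln2, "pop1")
  expect_equal(sum(sfs2$xi), 0L)
  expect_equal(sfs2$unpolarized, 1L)

  # ingroup-triallelic sites are excluded with a warning
  aln3 <- pop_alignment(c("AAAA", "AAGA", "AACA", "AAAA"),
                        c("s1", "s2", "s3", "og"),
                        c(rep("pop1", 3), "outgroup"))
  expect_warning(sfs3 <- polarize(aln3, "pop1"), ">2 alleles")
  expect_equal(sfs3$triallelic, 1L)
})

test_that("haplotypes with more than three indels in sites are excluded", {
  seqs <- c("ACGTACGTACGTACGTACGT",
            "ACGTACGTACGTACGTACGT",
            "AC----GTACGTACGTACGT",   # 4 gaps inside the site
            "ACGTACGCACGTACGTACGT",
            "ACGTACGTACGTACGTACGT")
  aln <- pop_alignment(seqs, c(paste0("s", 1:4), "og"),
                       c(rep("pop1", 4), "outgroup"))
  sites <- data.frame(start = 0L, end = 10L)
  sfs <- polarize(aln, "pop1", sites = sites)
  expect_equal(sfs$excluded_haplotypes, "s3")
  expect_equal(sfs$n, 3L)
  expect_equal(sfs$daf$derived_count, 1L)
})

test_that("SNP density is the count over the interval length and adds up", {
  withr::local_seed(73)
  anc <- sample(c("A", "C", "G", "T"), 42, TRUE)
  mat <- matrix(rep(anc, each = 4), 4)
  mat[1, 3] <- setdiff(c("A", "C", "G", "T"), anc[3])[1]
  mat[2, 15] <- setdiff(c("A", "C", "G", "T"), anc[15])[1]
  aln <- pop_alignment(apply(mat, 1, paste, collapse = ""))
  expect_equal(snp_density(aln, "ingroup", c(0, 21)), 2 / 21)
  expect_equal(snp_density(aln, "ingroup", c(21, 42)), 0)
  s1 <- snp_density(aln, "ingroup", c(0, 21)) * 21
  s2 <- snp_density(aln, "ingroup", c(21, 42)) * 21
  expect_equal((s1 + s2) / 42, snp_density(aln, "ingroup", c(0, 42)))
  expect_error(snp_density(aln, "ingroup", c(5, 5)), "coordinate error")
  # gap polymorphism only counts in indel-inclusive mode
  mat2 <- mat; mat2[1, 30] <- "-"
  aln2 <- pop_alignment(apply(mat2, 1, paste, collapse = ""))
  expect_equal(snp_density(aln2, "ingroup", c(21, 42)), 0)
  expect_equal(snp_density(aln2, "ingroup", c(21, 42), include_indels = TRUE),
               1 / 21)
})
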