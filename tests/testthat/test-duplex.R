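test_that("length normalization matches the published duplex table", {
  # 22-nt site haplotypes against the 22-nt miRNA: en = e / log10(m n)
  printed <- rbind(c(-34.68, -12.92), c(-31.04, -11.56), c(-31.18, -11.61),
                   c(-27.97, -10.42), c(-29.96, -11.16), c(-22.99, -8.56),
                   c(-22.42, -8.35), c(-18.95, -7.06))
  for (i in seq_len(nrow(printed))) {
    expect_equal(round(normalize_mfe(printed[i, 1], 22, 22), 2),
                 printed[i, 2])
  }
  expect_equal(normalize_mfe(0, 22, 22), 0)
  expect_error(normalize_mfe(-10, 1, 22), "domain error")
  expect_true(is.na(normalize_mfe(NA_real_, 22, 22)))
})

test_that("built-in engine matches a hand-summed helix from its own table", {
  p <- duplex_params()
  mi <- "GGCGCC"
  tg <- reverse_complement_rna(mi)      # GGCGCC again (palindrome)
  hand <- p$init +
    p$stack[["GG/CC"]] + p$stack[["GC/CG"]] + p$stack[["CG/GC"]] +
    p$stack[["GC/CG"]] + p$stack[["GG/CC"]]
  expect_equal(duplex_mfe(mi, tg), hand)

  # helix with terminal A:U pairs picks up the closing penalty at both ends
  mi2 <- "AGGCCU"
  tg2 <- reverse_complement_rna(mi2)
  # stacks AG/UC and CC/GG are the 180-degree rotations of CU/GA and GG/CC
  hand2 <- p$init + 2 * p$terminal_au +
    p$stack[["CU/GA"]] + p$stack[["GG/CC"]] + p$stack[["GC/CG"]] +
    p$stack[["GG/CC"]] + p$stack[["CU/GA"]]
  expect_equal(duplex_mfe(mi2, tg2), hand2)
})

test_that("duplex energies behave monotonically and flag no-duplex input", {
  expect_true(is.na(duplex_mfe("AAAAAA", "AAAAAA")))
  expect_error(duplex_mfe("", "ACGU"), "input error")

  mi <- "UUCCACAGCUUUCUUGAACUGG"
  tgt <- reverse_complement_rna(mi)
  e0 <- duplex_mfe(mi, tgt)
  tgt_mm <- tgt
  substr(tgt_mm, 11, 11) <- setdiff(c("A", "C", "G", "U"),
                                    substr(tgt, 11, 11))[1]
  expect_lt(e0, duplex_mfe(mi, tgt_mm))
  # rotating the duplex (swap strand roles) leaves the energy unchanged
  expect_equal(duplex_mfe(mi, tgt), duplex_mfe(tgt, mi))
})

test_that("external cofold engine runs and broadly agrees with builtin", {
  mi <- "UUCCACAGCUUUCUUGAACUGG"
  tgt <- reverse_complement_rna(mi)
  e_cof <- duplex_mfe(mi, tgt, engine = "rnacofold")
  expect_lt(e_cof, -20)
  expect_lt(abs(e_cof - duplex_mfe(mi, tgt)), 10)
})

test_that("variant classification follows the three-category scheme", {
  mi <- random_rna(21)
  site <- reverse_complement_rna(mi)
  flip <- function(s, p, to = NULL) {
    # substitute the site base opposite miRNA position p
    ch <- strsplit(s, "")[[1]]
    j <- length(ch) - p + 1
    ch[j] <- if (is.null(to))
      setdiff(c("A", "C", "G", "U"),
              c(ch[j], mirsel:::.RNA_COMP[[substr(mi, p, p)]]))[1] else to
    paste(ch, collapse = "")
  }
  ref <- pair_profile(mi, site)

  # match -> mismatch at p = 10 disrupts the seed rule: disruptive, lost
  eff <- classify_variant(ref, pair_profile(mi, flip(site, 10)), 10)
  expect_equal(eff$category, "match->disruptive-mismatch")
  expect_equal(eff$site_fate, "lost")

  # match -> G:U at p = 16 keeps the filter passing: nondisruptive, retained
  gu <- if (substr(mi, 16, 16) == "G") "U" else if (substr(mi, 16, 16) == "U")
    "G" else NA
  if (!is.na(gu)) {
    eff2 <- classify_variant(ref, pair_profile(mi, flip(site, 16, gu)), 16)
    expect_equal(eff2$category, "match->nondisruptive-mismatch")
    expect_equal(eff2$site_fate, "retained")
  }
  alt16 <- pair_profile(mi, flip(site, 16))
  eff2b <- classify_variant(ref, alt16, 16)
  expect_equal(eff2b$category, "match->nondisruptive-mismatch")
  expect_equal(eff2b$site_fate, "retained")

  # variant at an already-mismatched position cannot change the site fate
  alt16b <- pair_profile(mi, flip(flip(site, 16), 16))
  if (!identical(alt16$states, alt16b$states)) {
    eff3 <- classify_variant(alt16, alt16b, 16)
    expect_equal(eff3$category, "within-mismatch")
    expect_equal(eff3$site_fate, "retained")
  }
  expect_error(classify_variant(ref, ref, 5), "contract error")
})

test_that("fate calls are consistent with independent filter evaluation", {
  withr::local_seed(113)
  mi <- random_rna(21)
  site <- reverse_complement_rna(mi)
  for (i in 1:20) {
    nmut <- sample(0:4, 1)
    ch <- strsplit(site, "")[[1]]
    if (nmut > 0) {
      at <- sample(21, nmut)
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
    }
    refp <- pair_profile(mi, paste(ch, collapse = ""))
    p <- sample(21, 1)
    j <- 22 - p
    ch2 <- ch
    ch2[j] <- sample(setdiff(c("A", "C", "G", "U"), ch[j]), 1)
    altp <- pair_profile(mi, paste(ch2, collapse = ""))
    if (identical(refp$states, altp$states)) next
    eff <- classify_variant(refp, altp, p)
    rv <- evaluate_filter(refp)$passed
    av <- evaluate_filter(altp)$passed
    want <- if (rv && av) "retained" else if (rv) "lost" else
      if (av) "gained" else "none"
    expect_equal(eff$site_fate, want)
  }
})

test_that("haplotype report orders, deduplicates and tracks mismatch load", {
  haps <- c("CCGUCCCAUAAUAUAAGGGAUU",   # printed target-region haplotypes
            "CUGUCCCAUAAUAUAAGGGAUU",
            "CCGUCCCAUAAUAUAAGG-AUU",
            "CCAUCCCAUAAUAUAAGGGAUU",
            "CCGUCUCAUAAUAUAAGGAAUU")
  mir <- reverse_complement_rna(haps[1])  # synthetic stand-in miRNA
  rep <- haplotype_report(mir, haps)
  expect_equal(nrow(rep), 5L)
  expect_equal(rep$mismatches[1], 0L)
  expect_true(all(rep$m == 22) && all(rep$n == 22))
  # energy weakens (rises toward 0) with the mismatch load
  expect_true(all(diff(rep$e[order(rep$mismatches)]) >= 0 |
                    diff(rep$mismatches[order(rep$mismatches)]) == 0))
  expect_lt(max(rep$e[rep$mismatches == 0]), min(rep$e[rep$mismatches == 1]))
  expect_lt(max(rep$e[rep$mismatches == 1]), min(rep$e[rep$mismatches == 2]))
  expect_true(all(diff(abs(rep$e)) <= 0))  # ordered by descending |e|
  expect_equal(rep$en, round(rep$e / log10(484), 2))

  dup <- haplotype_report(mir, c(haps[1], haps[1], haps[2]))
  expect_equal(nrow(dup), 2L)
  expect_equal(dup$multiplicity[dup$mismatches == 0], 2L)

  single <- haplotype_report(mir, haps[1])
  expect_equal(nrow(single), 1L)
  expect_true(single$passes_filter)
})
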