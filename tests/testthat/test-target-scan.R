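mi21 <- "UUCCACAGCUUUCUUGAACUG"

test_that("pairing profile recovers perfect and singly-disrupted duplexes", {
  site <- reverse_complement_rna(mi21)
  prof <- pair_profile(mi21, site)
  expect_true(all(prof$states == "match"))
  expect_equal(prof$penalty, 0)

  # break pairing opposite miRNA position 10 (site index m - p + 1)
  p <- 10L
  ch <- strsplit(site, "")[[1]]
  partner <- nchar(site) - p + 1L
  ch[partner] <- setdiff(c("A", "C", "G", "U"),
                         c(ch[partner],
                           mirsel:::.RNA_COMP[[substr(mi21, p, p)]]))[1]
  prof2 <- pair_profile(mi21, paste(ch, collapse = ""))
  expect_equal(unname(which(prof2$states != "match")), 10L)

  expect_error(pair_profile(mi21, substr(site, 1, 17)), "scan error")
  expect_error(pair_profile("", site), "scan error")
})

test_that("single-gap placement matches exhaustive enumeration", {
  withr::local_seed(31)
  pen <- c(match = 0, GU = 0.5, mismatch = 1, gap = 1)
  for (rep in 1:10) {
    mi <- random_rna(21)
    site <- reverse_complement_rna(mi)
    drop_at <- sample(nchar(site), 1)
    short <- paste0(substr(site, 1, drop_at - 1),
                    substr(site, drop_at + 1, nchar(site)))
    prof <- pair_profile(mi, short)
    expect_equal(length(prof$gap_at), 1L)
    # brute force every gap position independently
    mic <- strsplit(mi, "")[[1]]
    sr <- rev(strsplit(short, "")[[1]])
    penalties <- vapply(1:21, function(j) {
      st <- character(21); st[j] <- "gap"; k <- 0
      for (p in (1:21)[-j]) {
        k <- k + 1
        st[p] <- mirsel:::.pair_state(mic[p], sr[k])
      }
      sum(pen[st])
    }, numeric(1))
    expect_equal(prof$penalty, min(penalties))
    best <- which(penalties == min(penalties))
    expect_equal(prof$gap_at, max(best))  # tie toward the miRNA 3' end
  }
})

test_that("each positional rule is triggered by its targeted construction", {
  base <- rep("match", 21)
  ok <- evaluate_filter(base)
  expect_true(ok$passed); expect_equal(ok$score, 0)
  expect_length(ok$violated_rules, 0)

  s <- base; s[10] <- "mismatch"
  expect_true("pos10-11" %in% evaluate_filter(s)$violated_rules)
  s <- base; s[11] <- "GU"   # G:U counts as a mismatch for the rules
  expect_true("pos10-11" %in% evaluate_filter(s)$violated_rules)

  s <- base; s[c(2, 7)] <- "mismatch"
  expect_true("max1-pos2-12" %in% evaluate_filter(s)$violated_rules)

  s <- base; s[14:16] <- "mismatch"
  expect_true("max2-consec-post13" %in% evaluate_filter(s)$violated_rules)
  s <- base; s[14:15] <- "mismatch"; s[1] <- "mismatch"
  expect_false("max2-consec-post13" %in% evaluate_filter(s)$violated_rules)
  # inclusive reading: a run starting at position 13 counts
  s <- base; s[13:15] <- "mismatch"
  expect_true("max2-consec-post13" %in% evaluate_filter(s)$violated_rules)
  expect_false("max2-consec-post13" %in%
                 evaluate_filter(s, downstream_inclusive = FALSE)$violated_rules)

  s <- base; s[c(1, 4, 14, 17, 20)] <- "mismatch"
  v <- evaluate_filter(s)
  expect_true("max4-total" %in% v$violated_rules)
  expect_false(v$passed)
})

test_that("profiles with five or more mismatches never pass", {
  withr::local_seed(41)
  for (i in 1:50) {
    s <- rep("match", 21)
    s[sample(21, sample(5:9, 1))] <- sample(c("mismatch", "GU", "gap"),
                                            1)
    expect_false(evaluate_filter(s)$passed)
  }
})

test_that("degrading a profile never turns a failing verdict into a pass", {
  withr::local_seed(43)
  for (i in 1:100) {
    s <- rep("match", 21)
    nmm <- sample(0:5, 1)
    if (nmm > 0) s[sample(21, nmm)] <- sample(c("mismatch", "GU"), nmm,
                                              replace = TRUE)
    before <- evaluate_filter(s)$passed
    j <- sample(which(s == "match"), 1)
    s[j] <- sample(c("mismatch", "GU", "gap"), 1)
    after <- evaluate_filter(s)$passed
    expect_false(!before && after)
  }
})

test_that("transcript scan equals a brute-force per-window re-scan", {
  withr::local_seed(47)
  mi <- random_rna(21)
  tx <- random_rna(300)
  planted <- reverse_complement_rna(mi)
  tx <- paste0(substr(tx, 1, 120), planted, substr(tx, 142, 300))
  res <- scan_transcript(mi, tx, mirna_id = "m1")
  # the planted perfect site is the top hit at its coordinates
  expect_equal(res$start[1], 120)
  expect_equal(res$end[1], 141)
  expect_equal(res$score[1], 0)
  # brute force: evaluate every window of widths 20, 21, 22 independently
  n <- 21L; Lt <- nchar(tx)
  brute <- list()
  for (w in (n - 1L):(n + 1L)) {
    for (s in 0:(Lt - w)) {
      v <- evaluate_filter(pair_profile(mi, substr(tx, s + 1, s + w)))
      if (v$passed) brute[[length(brute) + 1L]] <- c(s, s + w, v$score)
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute[, 3], brute[, 1], brute[, 2]), , drop = FALSE]
  expect_equal(res$start, brute[, 1])
  expect_equal(res$end, brute[, 2])
  expect_equal(res$score, brute[, 3])
})

test_that("scan coordinates shift with a prepended prefix", {
  withr::local_seed(53)
  mi <- random_rna(21)
  tx <- paste0(random_rna(60), reverse_complement_rna(mi), random_rna(60))
  res1 <- scan_transcript(mi, tx)
  res2 <- scan_transcript(mi, paste0("ACGUA", tx))
  expect_equal(res2$start, res1$start + 5L)
  expect_equal(res2$score, res1$score)
})

test_that("two planted sites are both reported in coordinate order", {
  withr::local_seed(59)
  mi <- random_rna(21)
  site <- reverse_complement_rna(mi)
  tx <- paste0(random_rna(30), site, random_rna(50), site, random_rna(30))
  res <- scan_transcript(mi, tx)
  hits0 <- res[res$score == 0, ]
  expect_equal(hits0$start, c(30, 101))
})
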