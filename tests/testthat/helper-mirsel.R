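# shared fixture builders and independent oracles

random_alignment <- function(n, L, n_mut = max(1L, L %/% 10L),
                             missing = 0, locus_id = "rand",
                             population = "pop1", outgroup = FALSE) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ntot <- n + outgroup
  mat <- matrix(rep(anc, each = ntot), ntot)
  cols <- sample.int(L, min(n_mut, L))
  for (j in cols) {
    carriers <- sample.int(n, sample.int(n - 1L, 1L))
    mat[carriers, j] <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1L)
  }
  if (missing > 0) {
    idx <- sample.int(n * L, missing)
    mat[seq_len(n), ][idx] <- sample(c("-", "N"), missing, replace = TRUE)
  }
  pop <- c(rep_len(population, n), if (outgroup) "outgroup")
  pop_alignment(apply(mat, 1L, paste, collapse = ""),
                sample_id = paste0("s", seq_len(ntot)),
                population = pop, locus_id = locus_id)
}

# independent diversity oracle: complete deletion, then all-pairs Hamming
brute_diversity <- function(aln, population = NULL) {
  rows <- if (is.null(population)) which(aln$population != "outgroup")
  else which(aln$population %in% population)
  mat <- aln$mat[rows, , drop = FALSE]
  keep <- apply(mat, 2L, function(x) all(x %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat); L <- ncol(mat)
  S <- sum(apply(mat, 2L, function(x) length(unique(x)) > 1L))
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(mat[i, ] != mat[j, ]); np <- np + 1
  }
  list(S = S, pi = if (L > 0) tot / np else 0,
       theta_w = if (L > 0) S / (sum(1 / seq_len(n - 1)) * L) else 0,
       L_analyzed = L)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# independent re-statement of the four positional rules plus score cutoff
oracle_verdict <- function(states, cutoff = 3) {
  mm <- which(states != "match")
  ok <- TRUE; viol <- character(0)
  if (10 %in% mm || 11 %in% mm) viol <- c(viol, "pos10-11")
  if (sum(mm >= 2 & mm <= 12) > 1) viol <- c(viol, "max1-pos2-12")
  down <- mm[mm >= 13]
  if (length(down) >= 3) {
    consec <- 1; best <- 1
    for (i in seq_along(down)[-1]) {
      consec <- if (down[i] == down[i - 1] + 1) consec + 1 else 1
      best <- max(best, consec)
    }
    if (best > 2) viol <- c(viol, "max2-consec-post13")
  }
  if (length(mm) >= 5) viol <- c(viol, "max4-total")
  score <- sum(c(match = 0, GU = 0.5, mismatch = 1, gap = 1)[states])
  if (score > cutoff) viol <- c(viol, "score-cutoff")
  list(passed = length(viol) == 0, violated = viol, score = score)
}
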