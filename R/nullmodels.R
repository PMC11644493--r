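# nullmodels: dinucleotide-shuffle resampling null and neutral coalescent -----
#
# The resampling null realizes each dinucleotide-preserving shuffle of the
# reference sequence as a permutation of alignment COLUMNS, applied uniformly
# to every haplotype, so each SNP allele travels with its column ("restoring
# of original SNP alleles"). Total per-site pi, S and the SFS are therefore
# exactly preserved; only the spatial arrangement changes.

#' Dinucleotide-preserving shuffle as a position permutation
#'
#' Altschul-Erickson style Eulerian shuffle of a sequence: the dinucleotide
#' count table of the permuted sequence equals the original exactly, and the
#' first and last residues are fixed. Returned as a permutation of positions
#' `1..L` (new position `j` takes the character from `perm[j]`), so it can be
#' applied to alignment columns.
#'
#' @param reference_seq Single sequence (length >= 2). Any single-character
#'   alphabet works; ambiguity codes should be collapsed to the reference
#'   allele beforehand.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of class `position_permutation` with attributes
#'   `reference` and `shuffled`.
#' @export
dinucleotide_shuffle <- function(reference_seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- .chars(toupper(reference_seq))
  L <- length(x)
  if (L < 2L) stop("shuffle error: sequence length < 2")
  finish <- function(perm) {
    structure(as.integer(perm), class = "position_permutation",
              reference = paste(x, collapse = ""),
              shuffled = paste(x[perm], collapse = ""))
  }
  if (length(unique(x)) == 1L) return(finish(seq_len(L)))

  # edges: position i is the edge x[i] -> x[i+1]; group out-edges by source
  out <- split(seq_len(L - 1L), x[seq_len(L - 1L)])
  verts <- names(out)
  terminal <- x[L]
  nonterm <- setdiff(verts, terminal)

  for (attempt in seq_len(10000L)) {
    last <- vapply(out[nonterm], function(e) e[sample.int(length(e), 1L)],
                   integer(1))
    # the chosen last edges must form an arborescence into the terminal node
    ok <- TRUE
    for (v in nonterm) {
      cur <- v; steps <- 0L
      while (cur != terminal && steps <= length(verts)) {
        if (!cur %in% nonterm) { ok <- FALSE; break }  # dead end w/o out-edge
        cur <- x[last[[cur]] + 1L]
        steps <- steps + 1L
      }
      if (!ok || cur != terminal) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == 10000L) stop("shuffle error: no Eulerian arrangement found")
  }

  order_list <- lapply(verts, function(v) {
    e <- out[[v]]
    if (v %in% nonterm) {
      rest <- setdiff(e, last[[v]])
      c(rest[sample.int(length(rest))], last[[v]])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(order_list) <- verts

  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  e_seq <- integer(L - 1L)
  cur <- x[1]
  for (s in seq_len(L - 1L)) {
    e <- order_list[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    e_seq[s] <- e
    cur <- x[e + 1L]
  }
  finish(c(1L, e_seq + 1L))
}

#' Dinucleotide count table of a sequence
#' @param seq Single sequence string.
#' @return Named integer vector of overlapping dinucleotide counts.
#' @export
dinucleotide_counts <- function(seq) {
  ch <- .chars(toupper(seq))
  if (length(ch) < 2L) return(integer(0))
  table(paste0(ch[-length(ch)], ch[-1]))
}

#' Shuffle-based null distribution for window diversity over an interval
#'
#' For each replicate one dinucleotide-preserving permutation is drawn from
#' the reference haplotype and applied to every haplotype's columns; the
#' replicate summary is the mean sliding-window `pi` over windows fully
#' inside `interval`. Whole-sequence per-site `pi` is identical across
#' replicates by construction. The empirical lower-tail p-value uses the
#' `(1 + #{null <= obs}) / (R + 1)` estimator.
#'
#' @param aln A [pop_alignment()].
#' @param reference Sample id of the reference haplotype whose sequence
#'   drives the shuffles.
#' @param interval 0-based half-open column interval (the binding site).
#' @param R Number of replicates.
#' @param w Sliding-window width.
#' @param population Population label(s) whose diversity is summarized
#'   (default: all non-outgroup haplotypes).
#' @param seed Optional seed.
#' @param outgroup_label Outgroup label.
#' @return Object of class `null_distribution`: `replicates` (length `R`),
#'   `observed`, `p_lower`, `whole_pi`, plus the parameters.
#' @export
resample_null <- function(aln, reference, interval, R = 1000L, w = 21L,
                          population = NULL, seed = NULL,
                          outgroup_label = "outgroup") {
  if (R < 1L) stop("parameter error: R < 1")
  if (!is.null(seed)) set.seed(seed)
  ref_row <- match(reference, aln$sample_id)
  if (is.na(ref_row)) stop("labeling error: reference haplotype '",
                           reference, "' not found")
  rows <- .pop_rows(aln, population, outgroup_label)
  if (length(rows) < 2L) stop("sample-size error: fewer than 2 haplotypes")
  mat <- aln$mat[rows, , drop = FALSE]
  L <- ncol(mat)
  if (interval[2] - interval[1] < w) {
    stop("window error: interval narrower than window")
  }
  refseq <- paste(aln$mat[ref_row, ], collapse = "")
  cp <- .column_pi(mat)

  win_starts <- interval[1]:(interval[2] - w)   # windows fully inside
  interval_mean <- function(pi_col, okv) {
    cs_pi <- c(0, cumsum(pi_col)); cs_ok <- c(0, cumsum(okv))
    num <- cs_pi[win_starts + w + 1L] - cs_pi[win_starts + 1L]
    den <- cs_ok[win_starts + w + 1L] - cs_ok[win_starts + 1L]
    mean(ifelse(den > 0, num / den, NA_real_), na.rm = TRUE)
  }
  observed <- interval_mean(cp$pi, cp$analyzed)
  whole_pi <- if (sum(cp$analyzed) > 0) sum(cp$pi) / sum(cp$analyzed) else 0

  reps <- numeric(R)
  for (r in seq_len(R)) {
    perm <- dinucleotide_shuffle(refseq)
    reps[r] <- interval_mean(cp$pi[perm], cp$analyzed[perm])
  }
  p <- (1 + sum(reps <= observed)) / (R + 1)
  structure(list(replicates = reps, observed = observed, p_lower = p,
                 whole_pi = whole_pi, R = R, w = w, interval = interval,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution: R=%d  observed=%.5f  null mean=%.5f  p(lower)=%.4g\n",
    x$R, x$observed, mean(x$replicates), x$p_lower))
  invisible(x)
}

# one neutral coalescent genealogy (Hudson model, time in units of 2N);
# returns branches below the root with subtree sizes, lengths and optionally
# tip membership
.coal_tree <- function(n, keep_tips = FALSE) {
  nn <- 2L * n - 1L
  size <- c(rep(1L, n), integer(n - 1L))
  len <- numeric(nn)
  memb <- if (keep_tips) c(as.list(seq_len(n)), vector("list", n - 1L))
  act <- seq_len(n)
  nxt <- n
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1L, k * (k - 1) / 2)
    len[act] <- len[act] + t
    pick <- sample.int(k, 2L)
    a <- act[pick[1]]; b <- act[pick[2]]
    nxt <- nxt + 1L
    size[nxt] <- size[a] + size[b]
    if (keep_tips) memb[[nxt]] <- c(memb[[a]], memb[[b]])
    act <- c(act[-pick], nxt)
    k <- k - 1L
  }
  keep <- seq_len(nn)[-nxt]                       # root carries no branch
  list(sizes = size[keep], lens = len[keep],
       members = if (keep_tips) memb[keep], total_len = sum(len[keep]))
}

# derived-allele counts only (fast path shared with h_test)
.sim_derived_counts <- function(n, S = NULL, theta = NULL) {
  tr <- .coal_tree(n, keep_tips = FALSE)
  if (is.null(S)) S <- stats::rpois(1L, theta / 2 * tr$total_len)
  if (S == 0L) return(integer(0))
  br <- sample.int(length(tr$lens), S, replace = TRUE, prob = tr$lens)
  tr$sizes[br]
}

#' Neutral coalescent simulator
#'
#' Standard Hudson coalescent without recombination: exponential coalescence
#' times with rate `choose(j, 2)` (time in units of `2N`). Under `theta`
#' mode, mutations are Poisson with rate `theta/2` per lineage per unit time
#' (so `E[S] = theta * a_{n-1}` and `E[pi] = theta` per locus); under
#' `fixed_S` mode exactly `S` mutations are placed on branches with
#' probability proportional to branch length.
#'
#' @param n Number of haplotypes (>= 2).
#' @param theta Population mutation parameter per locus (theta mode).
#' @param S Number of segregating sites (fixed-S mode). Give exactly one of
#'   `theta` / `S`.
#' @param R Number of replicates.
#' @param seed Optional seed.
#' @return List of `R` objects of class `coalescent_replicate`, each with
#'   `n`, `genotype` (`n x S` 0/1 matrix, ancestral/derived, columns ordered
#'   by position), `positions` (relative in `[0,1)`) and `counts`
#'   (per-site derived-allele counts).
#' @export
simulate_coalescent <- function(n, theta = NULL, S = NULL, R = 1L,
                                seed = NULL) {
  if (!.is_count(n) || n < 2) stop("parameter error: n must be >= 2")
  if (is.null(theta) == is.null(S)) {
    stop("parameter error: give exactly one of theta or S")
  }
  if (!is.null(theta) && theta <= 0) stop("parameter error: theta <= 0")
  if (!is.null(S) && !.is_count(S)) stop("parameter error: invalid S")
  if (R < 1L) stop("parameter error: R < 1")
  if (!is.null(seed)) set.seed(seed)
  replicate(R, simplify = FALSE, {
    tr <- .coal_tree(n, keep_tips = TRUE)
    s <- if (is.null(S)) stats::rpois(1L, theta / 2 * tr$total_len) else S
    geno <- matrix(0L, nrow = n, ncol = s)
    if (s > 0L) {
      br <- sample.int(length(tr$lens), s, replace = TRUE, prob = tr$lens)
      for (j in seq_len(s)) geno[tr$members[[br[j]]], j] <- 1L
      pos <- stats::runif(s)
      o <- order(pos)
      geno <- geno[, o, drop = FALSE]
      pos <- pos[o]
    } else {
      pos <- numeric(0)
    }
    structure(list(n = n, genotype = geno, positions = pos,
                   counts = colSums(geno)),
              class = "coalescent_replicate")
  })
}

#' Mean pairwise differences of a coalescent replicate
#' @param rep A `coalescent_replicate`.
#' @return Average number of pairwise differences (the pi estimator of
#'   theta, per locus).
#' @export
replicate_pi <- function(rep) {
  n <- rep$n
  i <- rep$counts
  sum(2 * i * (n - i)) / (n * (n - 1))
}
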