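# popgen: per-region, per-population diversity and polarization ---------------
#
# Missing-data rule: complete deletion of columns containing '-' or 'N'
# within the analyzed rows (indels are not included in the analysis); the
# indel-inclusive mode exists only for SNP-density style counts. Reported
# per-kb values are per-site values times 1000. The outgroup is always
# excluded from per-population statistics.

.pop_rows <- function(aln, population = NULL, outgroup_label = "outgroup") {
  if (is.null(population)) which(aln$population != outgroup_label)
  else which(aln$population %in% population)
}

.slice_cols <- function(mat, interval) {
  if (is.null(interval)) return(mat)
  L <- ncol(mat)
  s <- interval[1]; e <- interval[2]
  if (!(.is_count(s) && .is_count(e)) || s >= e || e > L) {
    stop("coordinate error: interval [", s, ", ", e, ") outside 0..", L)
  }
  mat[, (s + 1L):e, drop = FALSE]
}

# per-column heterozygosity (unbiased, pairwise) and analyzed indicator
.column_pi <- function(mat) {
  n <- nrow(mat)
  L <- ncol(mat)
  ok <- colSums(mat == "-" | mat == "N") == 0L
  vary <- colSums(mat != mat[rep(1L, n), , drop = FALSE]) > 0L
  pi_col <- numeric(L)
  npairs <- n * (n - 1) / 2
  for (j in which(ok & vary)) {
    cnt <- tabulate(match(mat[, j], c("A", "C", "G", "T")), 4L)
    pi_col[j] <- (npairs - sum(choose(cnt, 2))) / npairs
  }
  seg <- pi_col > 0
  list(pi = pi_col, analyzed = ok, segregating = seg)
}

#' Diversity statistics for one region and one population
#'
#' Computes the number of segregating sites `S`, nucleotide diversity per
#' site `pi` (mean pairwise difference proportion over all haplotype pairs at
#' analyzed sites), Watterson's `theta_W = S / (a_{n-1} L_analyzed)` and the
#' per-analyzed-site SNP density, after complete deletion of columns
#' containing `-` or `N`.
#'
#' @param aln A [pop_alignment()].
#' @param population Population label(s) to pool; `NULL` pools every
#'   non-outgroup haplotype.
#' @param interval Optional 0-based half-open column interval.
#' @param outgroup_label Label excluded from per-population computation.
#' @return Object of class `diversity_stats` with fields `S`, `pi`,
#'   `theta_w`, `snp_density`, `L_analyzed`, `L`, `n`.
#' @export
diversity <- function(aln, population = NULL, interval = NULL,
                      outgroup_label = "outgroup") {
  rows <- .pop_rows(aln, population, outgroup_label)
  if (length(rows) < 2L) {
    stop("sample-size error: fewer than 2 haplotypes for population ",
         paste(population, collapse = "+"))
  }
  mat <- .slice_cols(aln$mat[rows, , drop = FALSE], interval)
  cp <- .column_pi(mat)
  L_an <- sum(cp$analyzed)
  S <- sum(cp$segregating)
  pi <- if (L_an > 0) sum(cp$pi) / L_an else 0
  a_n1 <- harmonic_number(length(rows) - 1L)
  theta_w <- if (L_an > 0) S / (a_n1 * L_an) else 0
  structure(list(S = S, pi = pi, theta_w = theta_w,
                 snp_density = if (L_an > 0) S / L_an else 0,
                 L_analyzed = L_an, L = ncol(mat), n = length(rows)),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "diversity_stats: n=%d  S=%d  pi=%.5f (%.2f/kb)  theta_W=%.5f  L=%d/%d\n",
    x$n, x$S, x$pi, 1000 * x$pi, x$theta_w, x$L_analyzed, x$L))
  invisible(x)
}

#' Divergence to the outgroup
#'
#' Mean, over ingroup haplotypes, of the per-site difference proportion to
#' the outgroup sequence at analyzed sites (columns where ingroup and
#' outgroup are all in `A,C,G,T`). The optional Jukes-Cantor correction is
#' off by default.
#'
#' @inheritParams diversity
#' @param jukes_cantor Apply the JC69 multiple-hit correction.
#' @return Divergence per site `k` (a single number).
#' @export
divergence <- function(aln, population = NULL, interval = NULL,
                       outgroup_label = "outgroup", jukes_cantor = FALSE) {
  og <- which(aln$population == outgroup_label)
  if (!length(og)) stop("labeling error: no outgroup haplotype '",
                        outgroup_label, "'")
  rows <- .pop_rows(aln, population, outgroup_label)
  if (!length(rows)) stop("labeling error: empty ingroup")
  mat <- .slice_cols(aln$mat[c(rows, og[1]), , drop = FALSE], interval)
  ni <- length(rows)
  ok <- colSums(mat == "-" | mat == "N") == 0L
  if (!any(ok)) return(NA_real_)
  ing <- mat[seq_len(ni), ok, drop = FALSE]
  out <- mat[ni + 1L, ok]
  k <- mean(rowMeans(ing != rep(out, each = ni)))
  if (jukes_cantor && k > 0) {
    if (k >= 0.75) stop("divergence too large for Jukes-Cantor correction")
    k <- -0.75 * log(1 - 4 * k / 3)
  }
  k
}

#' Sliding-window nucleotide diversity
#'
#' Window `i` covers columns `[i, i + w)`; per-window `pi` applies the same
#' complete-deletion rule within the window. The default width of 21 columns
#' matches the mean binding-site size.
#'
#' @inheritParams diversity
#' @param w Window width in columns.
#' @param step Step between window starts.
#' @return Data frame `window_start` (0-based), `pi` (`NA` where a window has
#'   no analyzed column).
#' @export
sliding_pi <- function(aln, population = NULL, w = 21L, step = 1L,
                       outgroup_label = "outgroup") {
  rows <- .pop_rows(aln, population, outgroup_label)
  if (length(rows) < 2L) stop("sample-size error: fewer than 2 haplotypes")
  mat <- aln$mat[rows, , drop = FALSE]
  L <- ncol(mat)
  if (L < w) stop("window error: alignment length ", L, " < window ", w)
  cp <- .column_pi(mat)
  starts <- seq.int(0L, L - w, by = step)
  cs_pi <- c(0, cumsum(cp$pi))
  cs_ok <- c(0, cumsum(cp$analyzed))
  num <- cs_pi[starts + w + 1L] - cs_pi[starts + 1L]
  den <- cs_ok[starts + w + 1L] - cs_ok[starts + 1L]
  data.frame(window_start = starts, pi = ifelse(den > 0, num / den, NA_real_))
}

#' Construct a polarized site-frequency spectrum
#'
#' @param xi Numeric vector of site counts; either length `n - 1` (slot `i`
#'   holds the number of sites with derived-allele count `i`) or a vector of
#'   per-site derived-allele counts when `tabulated = FALSE`.
#' @param n Haplotype count.
#' @param unpolarized Number of excluded (unpolarizable) segregating sites.
#' @param tabulated Interpret `xi` as already tabulated.
#' @return Object of class `polarized_sfs`.
#' @export
polarized_sfs <- function(xi, n, unpolarized = 0L, tabulated = TRUE) {
  stopifnot(n >= 2)
  if (!tabulated) xi <- tabulate(xi, nbins = n - 1L)
  if (length(xi) != n - 1L) stop("xi must have length n - 1")
  if (any(xi < 0)) stop("negative site counts")
  structure(list(n = as.integer(n),
                 xi = stats::setNames(as.integer(xi), seq_len(n - 1L)),
                 unpolarized = as.integer(unpolarized)),
            class = "polarized_sfs")
}

#' @export
print.polarized_sfs <- function(x, ...) {
  cat("polarized_sfs: n =", x$n, " polarized sites =", sum(x$xi),
      " unpolarized =", x$unpolarized, "\n")
  invisible(x)
}

#' Polarize segregating sites with an outgroup
#'
#' A biallelic ingroup site is polarized only if the outgroup allele equals
#' one of the two ingroup alleles; the other allele is then derived. Sites
#' where the outgroup carries a gap, `N` or a third allele are counted as
#' `unpolarized`; ingroup columns containing `-`/`N` follow the complete
#' deletion rule; ingroup-triallelic sites are excluded with a warning.
#' Haplotypes with more than `max_indels` gap characters inside the supplied
#' binding-site intervals are excluded before frequencies are computed.
#'
#' @inheritParams diversity
#' @param sites Optional data frame with `start`/`end` columns (0-based
#'   half-open) delimiting binding sites for the indel-exclusion rule.
#' @param max_indels Exclusion threshold (default 3).
#' @return Object of class `polarized_sfs`, with the additional fields
#'   `daf` (data frame: `col`, `ancestral`, `derived`, `derived_count`,
#'   `daf`), `excluded_haplotypes` and `triallelic`.
#' @export
polarize <- function(aln, population = NULL, outgroup_label = "outgroup",
                     interval = NULL, sites = NULL, max_indels = 3L) {
  og <- which(aln$population == outgroup_label)
  if (!length(og)) stop("labeling error: no outgroup haplotype '",
                        outgroup_label, "'")
  rows <- .pop_rows(aln, population, outgroup_label)
  excluded <- character(0)
  if (!is.null(sites) && nrow(sites)) {
    cols <- unlist(lapply(seq_len(nrow(sites)),
                          function(i) (sites$start[i] + 1L):sites$end[i]))
    gap_counts <- rowSums(aln$mat[rows, cols, drop = FALSE] == "-")
    drop <- gap_counts > max_indels
    excluded <- aln$sample_id[rows[drop]]
    rows <- rows[!drop]
  }
  if (length(rows) < 2L) stop("sample-size error: fewer than 2 haplotypes")
  mat <- .slice_cols(aln$mat[c(rows, og[1]), , drop = FALSE], interval)
  ni <- length(rows)
  offset <- if (is.null(interval)) 0L else interval[1]
  counts <- integer(0); cols_out <- integer(0)
  anc <- character(0); der <- character(0)
  unpolarized <- 0L; triallelic <- 0L
  for (j in seq_len(ncol(mat))) {
    x <- mat[seq_len(ni), j]
    if (any(x == "-" | x == "N")) next       # complete deletion
    alleles <- unique(x)
    if (length(alleles) == 1L) next
    if (length(alleles) > 2L) { triallelic <- triallelic + 1L; next }
    o <- mat[ni + 1L, j]
    if (!(o %in% alleles)) { unpolarized <- unpolarized + 1L; next }
    d <- setdiff(alleles, o)
    cnt <- sum(x == d)
    cols_out <- c(cols_out, j - 1L + offset)
    anc <- c(anc, o); der <- c(der, d); counts <- c(counts, cnt)
  }
  if (triallelic > 0L) {
    warning(triallelic, " ingroup site(s) with >2 alleles excluded")
  }
  sfs <- polarized_sfs(counts, n = ni, unpolarized = unpolarized,
                       tabulated = FALSE)
  sfs$daf <- data.frame(col = cols_out, ancestral = anc, derived = der,
                        derived_count = counts, daf = counts / ni,
                        stringsAsFactors = FALSE)
  sfs$excluded_haplotypes <- excluded
  sfs$triallelic <- triallelic
  sfs
}

#' SNP density over an interval
#'
#' `S(interval) / length(interval)` for one population; with
#' `include_indels = TRUE`, columns polymorphic for a gap character also
#' count as segregating (columns are then compared over non-`N` characters
#' instead of being deleted).
#'
#' @inheritParams diversity
#' @param interval 0-based half-open column interval (required).
#' @param include_indels Count gap polymorphisms as segregating sites.
#' @return SNPs per bp (single number).
#' @export
snp_density <- function(aln, population = NULL, interval,
                        include_indels = FALSE, outgroup_label = "outgroup") {
  if (missing(interval) || interval[2] <= interval[1]) {
    stop("coordinate error: zero-length or missing interval")
  }
  rows <- .pop_rows(aln, population, outgroup_label)
  if (length(rows) < 2L) stop("sample-size error: fewer than 2 haplotypes")
  mat <- .slice_cols(aln$mat[rows, , drop = FALSE], interval)
  if (include_indels) {
    S <- sum(apply(mat, 2L, function(x) {
      length(unique(x[x != "N"])) >= 2L
    }))
  } else {
    cp <- .column_pi(mat)
    S <- sum(cp$segregating)
  }
  S / (interval[2] - interval[1])
}
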