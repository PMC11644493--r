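# duplex: miRNA:target hybridization energy and variant classification --------
#
# The built-in engine is a nearest-neighbor duplex model: intermolecular
# Watson-Crick pairing only (no intramolecular structure, no G:U pairs --
# consistent with the target filter, which penalizes wobbles), stacking free
# energies for adjacent pairs from the bundled Watson-Crick parameter table
# (Xia et al. 1998, 37C, kcal/mol), a simple affine penalty for bulges and
# internal loops, duplex initiation, and a terminal A:U penalty. It is the
# minimum over duplex alignments of the summed terms. An external RNAcofold
# engine can be selected when the ViennaRNA binary is on the PATH.

# canonical Watson-Crick stack table; key = top strand 5'->3' dinucleotide,
# "/", bottom strand bases aligned beneath (read 3'->5')
.WC_STACK <- c(
  "AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
  "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
  "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26, "GC/CG" = -3.42)

#' Built-in duplex engine parameters
#'
#' The bundled nearest-neighbor table and penalties used by the built-in
#' engine of [duplex_mfe()], exposed so that helix energies can be
#' hand-summed and audited.
#'
#' @return List with `stack` (named kcal/mol values, key
#'   `XY/WZ` = top dinucleotide 5'->3' over bottom bases read 3'->5'),
#'   `init` (duplex initiation), `terminal_au` (per terminal A:U pair),
#'   `loop_init`, `loop_per_nt` (affine bulge/internal-loop penalty) and
#'   `max_loop` (largest unpaired stretch considered per strand).
#' @export
duplex_params <- function() {
  list(stack = .WC_STACK, init = 4.09, terminal_au = 0.45,
       loop_init = 3.0, loop_per_nt = 0.3, max_loop = 10L)
}

.wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

# stack energy between adjacent pairs (x1:y1) then (x2:y2) along the miRNA;
# the duplex read in the other direction is the same stack rotated 180 deg
.stack_energy <- function(x1, x2, y1, y2) {
  k1 <- paste0(x1, x2, "/", y1, y2)
  if (!is.na(.WC_STACK[k1])) return(unname(.WC_STACK[k1]))
  k2 <- paste0(y2, y1, "/", x2, x1)
  unname(.WC_STACK[k2])
}

.builtin_duplex_mfe <- function(mi, tg) {
  a <- .chars(.norm_rna(mi))
  b <- rev(.chars(.norm_rna(tg)))  # antiparallel: indices advance together
  n <- length(a); m <- length(b)
  p <- duplex_params()
  pairable <- outer(a, b, function(x, y) .wc_partner[x] == y)
  if (!any(pairable, na.rm = TRUE)) return(NA_real_)
  au_pen <- function(i, j) if (a[i] %in% c("A", "U")) p$terminal_au else 0
  D <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!isTRUE(pairable[i, j])) next
    best <- p$init + au_pen(i, j)       # open the duplex at this pair
    for (di in seq_len(min(i - 1L, p$max_loop + 1L))) {
      for (dj in seq_len(min(j - 1L, p$max_loop + 1L))) {
        prev <- D[i - di, j - dj]
        if (!is.finite(prev)) next
        link <- if (di == 1L && dj == 1L) {
          .stack_energy(a[i - 1L], a[i], b[j - 1L], b[j])
        } else {
          p$loop_init + p$loop_per_nt * ((di - 1L) + (dj - 1L))
        }
        cand <- prev + link
        if (cand < best) best <- cand
      }
    }
    D[i, j] <- best
  }
  close_pen <- outer(seq_len(n), seq_len(m),
                     Vectorize(function(i, j) au_pen(i, j)))
  e <- suppressWarnings(min(D + close_pen))
  if (!is.finite(e) || e > 0) NA_real_ else e
}

.rnacofold_mfe <- function(mi, tg) {
  bin <- Sys.which("RNAcofold")
  if (!nzchar(bin)) stop("RNAcofold not found on PATH")
  out <- system2(bin, args = "--noPS",
                 input = paste0(.norm_rna(mi), "&", .norm_rna(tg)),
                 stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("\\((\\s*-?[0-9.]+)\\)\\s*$", line))[[1]]
  if (length(m) < 2L) stop("could not parse RNAcofold output: ", line)
  as.numeric(m[2])
}

#' Minimum free energy of the miRNA:target heterodimer
#'
#' @param mirna_seq Mature miRNA 5'->3'.
#' @param target_seq Target site 5'->3' (gap characters are removed).
#' @param engine `"builtin"` (nearest-neighbor duplex model, the default) or
#'   `"rnacofold"` (external ViennaRNA cofold binary).
#' @return MFE in kcal/mol (`<= 0`), or `NA` when no stabilizing duplex
#'   exists (the "no duplex" sentinel).
#' @export
duplex_mfe <- function(mirna_seq, target_seq,
                       engine = c("builtin", "rnacofold")) {
  engine <- match.arg(engine)
  tg <- gsub("-", "", target_seq)
  if (!nzchar(mirna_seq) || !nzchar(tg)) stop("input error: empty sequence")
  switch(engine,
         builtin = .builtin_duplex_mfe(mirna_seq, tg),
         rnacofold = .rnacofold_mfe(mirna_seq, tg))
}

#' Length-normalized hybridization energy
#'
#' `en = e / log10(m * n)` with `m` the length of the target sequence
#' searched and `n` the miRNA length, so duplexes of different lengths are
#' comparable. Values are rounded only at the reporting layer (two decimals
#' in the haplotype report).
#'
#' @param e Minimum free energy in kcal/mol (may be `NA`, the no-duplex
#'   sentinel, which propagates).
#' @param m Target sequence length (>= 2).
#' @param n_mirna miRNA length (>= 2).
#' @return Normalized energy (same sign as `e`).
#' @export
normalize_mfe <- function(e, m, n_mirna) {
  if (!(m >= 2 && n_mirna >= 2) || m * n_mirna <= 1) {
    stop("domain error: need m >= 2, n >= 2")
  }
  e / log10(m * n_mirna)
}

#' Classify a single variant inside a binding site
#'
#' Given the pairing profiles of the reference and alternate haplotype and
#' the miRNA position where they differ, assigns the three-way category:
#' a variant at an already-mismatched position is `within-mismatch` (it
#' cannot gain or lose the target); a match turned into a mismatch that
#' leaves the filter passing is `nondisruptive-mismatch`; one that makes a
#' filter rule fail is `disruptive-mismatch`. The site fate compares the
#' filter verdicts of both profiles.
#'
#' @param ref_profile,alt_profile [pair_profile()] results differing at
#'   `mirna_position` (single-variant contract; decompose multi-variant
#'   haplotypes upstream).
#' @param mirna_position 1-based miRNA position of the variant.
#' @param ... Passed to [evaluate_filter()].
#' @return Object of class `variant_effect`: `category`, `site_fate`
#'   (`retained`, `lost`, `gained` or `none`), and both verdicts.
#' @export
classify_variant <- function(ref_profile, alt_profile, mirna_position, ...) {
  rs <- .as_states(ref_profile); as <- .as_states(alt_profile)
  if (identical(rs, as)) stop("contract error: profiles are identical")
  p <- mirna_position
  ref_v <- evaluate_filter(ref_profile, ...)
  alt_v <- evaluate_filter(alt_profile, ...)
  category <- if (rs[p] != "match") {
    "within-mismatch"
  } else if (alt_v$passed) {
    "match->nondisruptive-mismatch"
  } else {
    "match->disruptive-mismatch"
  }
  site_fate <- if (ref_v$passed && alt_v$passed) "retained"
  else if (ref_v$passed && !alt_v$passed) "lost"
  else if (!ref_v$passed && alt_v$passed) "gained"
  else "none"
  structure(list(category = category, site_fate = site_fate,
                 ref_verdict = ref_v, alt_verdict = alt_v,
                 mirna_position = p),
            class = "variant_effect")
}

#' @export
print.variant_effect <- function(x, ...) {
  cat("variant_effect @ p=", x$mirna_position, ": ", x$category,
      " / site ", x$site_fate, "\n", sep = "")
  invisible(x)
}

#' Per-haplotype duplex report for a binding site
#'
#' One row per distinct haplotype (duplicates collapsed with a multiplicity
#' column), with the duplex MFE, its length normalization (target length `m`
#' counts gap characters, matching how phased site haplotypes are printed),
#' the filter verdict and the mismatch count; rows ordered by descending
#' `|e|`. A note records mismatch counts realized with more than one
#' distinct energy (mismatch position matters, not just count).
#'
#' @param mirna_seq Mature miRNA 5'->3'.
#' @param haplotype_seqs Character vector of site haplotypes (may contain
#'   `-`).
#' @param engine Passed to [duplex_mfe()].
#' @param digits Rounding applied to the reported `e`/`en` columns.
#' @return Data frame `haplotype`, `multiplicity`, `e`, `en`, `m`, `n`,
#'   `passes_filter`, `mismatches`, with attribute `note`.
#' @export
haplotype_report <- function(mirna_seq, haplotype_seqs, engine = "builtin",
                             digits = 2) {
  if (!length(haplotype_seqs)) stop("no haplotypes")
  haps <- vapply(haplotype_seqs, .norm_rna, character(1), USE.NAMES = FALSE)
  tab <- table(factor(haps, levels = unique(haps)))
  n_mi <- nchar(.norm_rna(mirna_seq))
  rows <- lapply(names(tab), function(h) {
    e <- duplex_mfe(mirna_seq, h, engine = engine)
    m <- nchar(h)
    prof <- pair_profile(mirna_seq, gsub("-", "", h))
    v <- evaluate_filter(prof)
    data.frame(haplotype = h, multiplicity = as.integer(tab[[h]]),
               e = e, en = normalize_mfe(e, m, n_mi),
               m = m, n = n_mi,
               passes_filter = v$passed, mismatches = v$total_mismatches,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$e), out$haplotype, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out$e <- round(out$e, digits)
  out$en <- round(out$en, digits)
  dup_mm <- vapply(split(out$e, out$mismatches),
                   function(e) length(unique(e[!is.na(e)])) > 1L, logical(1))
  attr(out, "note") <- if (any(dup_mm)) {
    paste0("equal mismatch counts with distinct energies: ",
           paste(names(dup_mm)[dup_mm], collapse = ", "))
  } else ""
  out
}
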