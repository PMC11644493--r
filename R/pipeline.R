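# pipeline: end-to-end analysis over a dataset --------------------------------

#' Two-group comparison used throughout the report
#'
#' `rank-sum`: two-sided Wilcoxon rank sum; exact enumeration when both
#' groups have at most 8 untied values, normal approximation with continuity
#' correction otherwise. `chi-square`: each group is a pair
#' `(segregating sites, total sites)`; the test is run on the implied 2x2
#' table of segregating vs non-segregating sites. When every value is
#' identical across both groups, `p = 1` by convention.
#'
#' @param values_a,values_b Numeric vectors (rank-sum) or length-2 count
#'   pairs `c(segregating, total)` (chi-square).
#' @param kind `"rank-sum"` or `"chi-square"`.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b,
                           kind = c("rank-sum", "chi-square")) {
  kind <- match.arg(kind)
  if (kind == "rank-sum") {
    if (!length(values_a) || !length(values_b)) stop("empty group")
    pooled <- c(values_a, values_b)
    if (length(unique(pooled)) == 1L) return(1)
    exact <- length(values_a) <= 8L && length(values_b) <= 8L &&
      !anyDuplicated(pooled)
    suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact,
                         correct = TRUE)$p.value)
  } else {
    stopifnot(length(values_a) == 2L, length(values_b) == 2L)
    tab <- rbind(c(values_a[1], values_a[2] - values_a[1]),
                 c(values_b[1], values_b[2] - values_b[1]))
    if (any(tab < 0)) stop("segregating count exceeds total")
    if (all(tab[, 1] == 0) || all(tab[, 2] == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Percent reduction of diversity in cultivated relative to wild rice
#'
#' `100 * (1 - pi_cultivated / pi_wild)`; e.g. 0.004 vs 0.009 is a 56%
#' reduction (reported rounded to whole percent).
#'
#' @param pi_cultivated,pi_wild Diversity estimates on the same scale.
#' @return Percentage (unrounded).
#' @export
percent_reduction <- function(pi_cultivated, pi_wild) {
  if (pi_wild <= 0) return(NA_real_)
  100 * (1 - pi_cultivated / pi_wild)
}

.DEFAULT_GROUPS <- list(
  IND = "indica", TEM = "temperate_japonica", TRO = "tropical_japonica",
  JAP = c("temperate_japonica", "tropical_japonica"),
  ON = "nivara", OR = "rufipogon",
  cultivated = c("indica", "temperate_japonica", "tropical_japonica"),
  wild = c("nivara", "rufipogon"))

.safe_div <- function(aln, pops, interval = NULL) {
  tryCatch(diversity(aln, population = pops, interval = interval),
           error = function(e) NULL)
}

#' Run the full selection analysis on a dataset
#'
#' Orchestrates the per-locus, per-population diversity survey, the
#' conserved vs rice-specific summary (with the externally supplied
#' genome-wide background constants), the site-vs-flank polymorphism and
#' divergence comparisons, the derived-allele-frequency table, the Fay & Wu
#' H and MLHKA tests at rice-specific loci (conserved-class loci serve as
#' the neutral reference panel), the per-haplotype duplex report, SNP
#' density contrasts, and the percent diversity reduction per site class.
#' Flank regions are the within-locus sequence 5' and 3' of each site.
#'
#' @param dataset A `sim_dataset` (from [simulate_dataset()] or
#'   [read_dataset()]) or a directory path understood by [read_dataset()].
#' @param groups Named list mapping report columns to population labels.
#' @param background_pi_per_kb Genome-wide background diversity constants
#'   per kb, named `cultivated` and `wild` (supplied, never recomputed).
#' @param h_reps Null replicates for the H test.
#' @param seed Seed controlling the simulated nulls (the report is
#'   deterministic given inputs and seed).
#' @param engine Duplex engine for the haplotype table.
#' @return Object of class `analysis_report`: a list of data frames
#'   `diversity`, `table1`, `site_flank`, `table2_daf`, `table3_tests`,
#'   `table4_duplex`, `snp_contrasts`, `reductions`, plus `log` (filter
#'   decisions) and `settings`.
#' @export
run_all <- function(dataset, groups = .DEFAULT_GROUPS,
                    background_pi_per_kb = c(cultivated = 3.20, wild = 5.19),
                    h_reps = 1000L, seed = 1L, engine = "builtin") {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  set.seed(seed)
  alns <- dataset$alignments
  sites <- dataset$sites
  log_lines <- character(0)

  # ---- per-locus, per-group, per-region diversity ---------------------------
  div_rows <- list()
  for (locus in names(alns)) {
    aln <- alns[[locus]]
    L <- alignment_length(aln)
    srow <- sites[sites$locus == locus, , drop = FALSE]
    regions <- list(locus = NULL)
    if (nrow(srow)) {
      regions$site <- c(srow$start[1], srow$end[1])
      if (srow$start[1] > 0) regions$flank5 <- c(0L, srow$start[1])
      if (srow$end[1] < L) regions$flank3 <- c(srow$end[1], L)
    }
    for (g in names(groups)) {
      for (rg in names(regions)) {
        d <- .safe_div(aln, groups[[g]], regions[[rg]])
        if (is.null(d)) next
        k <- tryCatch(divergence(aln, groups[[g]], interval = regions[[rg]]),
                      error = function(e) NA_real_)
        div_rows[[length(div_rows) + 1L]] <- data.frame(
          locus = locus,
          class = if (nrow(srow)) srow$conservation_class[1] else NA,
          group = g, region = rg, n = d$n, S = d$S,
          pi = d$pi, pi_per_kb = 1000 * d$pi, theta_w = d$theta_w,
          k = k, snp_density = d$snp_density, L_analyzed = d$L_analyzed,
          stringsAsFactors = FALSE)
      }
    }
  }
  div <- do.call(rbind, div_rows)
  rownames(div) <- NULL

  msub <- function(grp, rgn, cls = NULL) {
    x <- div[div$group == grp & div$region == rgn, , drop = FALSE]
    if (!is.null(cls)) x <- x[x$class %in% cls, , drop = FALSE]
    x
  }

  # ---- Table-1 style: class means at site intervals + background ------------
  t1 <- do.call(rbind, lapply(c("cultivated", "wild"), function(grp) {
    s <- msub(grp, "site")
    data.frame(
      population = grp,
      background_pi_per_kb = unname(background_pi_per_kb[grp]),
      conserved_pi_per_kb = mean(s$pi_per_kb[s$class == "conserved"]),
      nonconserved_pi_per_kb = mean(s$pi_per_kb[s$class == "rice-specific"]),
      conserved_n_loci = sum(s$class == "conserved"),
      nonconserved_n_loci = sum(s$class == "rice-specific"),
      stringsAsFactors = FALSE)
  }))

  # ---- site vs flank comparisons (per class and group) ----------------------
  sf_rows <- list()
  for (grp in c("cultivated", "wild")) {
    for (cls in unique(stats::na.omit(sites$conservation_class))) {
      s <- msub(grp, "site", cls)
      f5 <- msub(grp, "flank5", cls); f3 <- msub(grp, "flank3", cls)
      if (!nrow(s)) next
      flank_pi <- c(f5$pi_per_kb, f3$pi_per_kb)
      p <- if (length(flank_pi) && nrow(s)) {
        compare_groups(s$pi_per_kb, flank_pi, "rank-sum")
      } else NA_real_
      sf_rows[[length(sf_rows) + 1L]] <- data.frame(
        group = grp, class = cls,
        site_pi_per_kb = mean(s$pi_per_kb),
        flank5_pi_per_kb = mean(f5$pi_per_kb),
        flank3_pi_per_kb = mean(f3$pi_per_kb),
        site_k = mean(s$k, na.rm = TRUE),
        flank5_k = mean(f5$k, na.rm = TRUE),
        flank3_k = mean(f3$k, na.rm = TRUE),
        rank_sum_p = p, stringsAsFactors = FALSE)
    }
  }
  site_flank <- do.call(rbind, sf_rows)

  # ---- Table-2 style DAF table at rice-specific sites -----------------------
  rs_sites <- sites[sites$conservation_class == "rice-specific", ,
                    drop = FALSE]
  daf_cols <- c("IND", "TEM", "TRO", "JAP", "ON", "OR")
  t2_rows <- list()
  for (i in seq_len(nrow(rs_sites))) {
    locus <- rs_sites$locus[i]
    aln <- alns[[locus]]
    interval <- c(rs_sites$start[i], rs_sites$end[i])
    all_sfs <- tryCatch(
      suppressWarnings(polarize(aln, interval = interval,
                                sites = rs_sites[i, , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(all_sfs) || !nrow(all_sfs$daf)) next
    if (length(all_sfs$excluded_haplotypes)) {
      log_lines <- c(log_lines, paste0(
        locus, ": excluded ", length(all_sfs$excluded_haplotypes),
        " haplotype(s) with >3 indels at binding sites"))
    }
    if (all_sfs$unpolarized > 0L) {
      log_lines <- c(log_lines, paste0(
        locus, ": ", all_sfs$unpolarized, " unpolarizable site(s)"))
    }
    for (v in seq_len(nrow(all_sfs$daf))) {
      row <- data.frame(locus = locus, col = all_sfs$daf$col[v],
                        ancestral = all_sfs$daf$ancestral[v],
                        derived = all_sfs$daf$derived[v],
                        stringsAsFactors = FALSE)
      for (g in daf_cols) {
        rows <- .pop_rows(aln, groups[[g]])
        x <- aln$mat[rows, all_sfs$daf$col[v] + 1L]
        ok <- !(x %in% c("-", "N"))
        row[[g]] <- if (any(ok)) {
          round(sum(x[ok] == all_sfs$daf$derived[v]) / sum(ok), 2)
        } else NA_real_
      }
      t2_rows[[length(t2_rows) + 1L]] <- row
    }
  }
  table2 <- if (length(t2_rows)) do.call(rbind, t2_rows) else
    data.frame(locus = character(0))

  # ---- Table-3 style neutrality tests ---------------------------------------
  ref_loci <- sites$locus[sites$conservation_class == "conserved"]
  taxa <- c("IND", "JAP", "TEM", "TRO", "ON", "OR")
  t3_rows <- list()
  for (i in seq_len(nrow(rs_sites))) {
    locus <- rs_sites$locus[i]
    for (tx in taxa) {
      pops <- groups[[tx]]
      sfs <- tryCatch(suppressWarnings(
        polarize(alns[[locus]], population = pops)), error = function(e) NULL)
      h_p <- NA_real_
      if (!is.null(sfs) && sum(sfs$xi) > 0) {
        h_p <- h_test(sfs, R = h_reps)$p_value
      }
      hka <- tryCatch({
        build <- function(lc, selected) {
          d <- diversity(alns[[lc]], population = pops)
          kk <- divergence(alns[[lc]], population = pops)
          data.frame(locus = lc, S = d$S,
                     D = round(kk * d$L_analyzed), n = d$n,
                     L = d$L_analyzed, selected = selected,
                     stringsAsFactors = FALSE)
        }
        tab <- do.call(rbind, c(lapply(ref_loci, build, selected = FALSE),
                                list(build(locus, selected = TRUE))))
        mlhka_fit(tab)
      }, error = function(e) NULL)
      t3_rows[[length(t3_rows) + 1L]] <- data.frame(
        locus = locus, taxon = tx, h_p = h_p,
        mlhka_p = if (is.null(hka)) NA_real_ else hka$p_value,
        k_hat = if (is.null(hka)) NA_real_ else unname(hka$k[locus]),
        stringsAsFactors = FALSE)
    }
  }
  table3 <- if (length(t3_rows)) do.call(rbind, t3_rows) else
    data.frame(locus = character(0))

  # ---- Table-4 style duplex report ------------------------------------------
  t4 <- list()
  for (i in seq_len(nrow(rs_sites))) {
    locus <- rs_sites$locus[i]
    aln <- alns[[locus]]
    rows <- .pop_rows(aln, NULL)
    seg <- extract_region(aln, rs_sites$start[i], rs_sites$end[i])
    haps <- apply(seg$mat[rows, , drop = FALSE], 1L, paste, collapse = "")
    rep_tab <- haplotype_report(dataset$mirnas[[rs_sites$mirna_id[i]]],
                                unname(haps), engine = engine)
    rep_tab <- cbind(locus = locus, rep_tab, stringsAsFactors = FALSE)
    t4[[length(t4) + 1L]] <- rep_tab
  }
  table4 <- if (length(t4)) do.call(rbind, t4) else
    data.frame(locus = character(0))

  # ---- SNP density contrasts and percent reductions -------------------------
  contrast <- function(grp) {
    con <- msub(grp, "site", "conserved")
    rsx <- msub(grp, "site", "rice-specific")
    if (!nrow(con) || !nrow(rsx)) return(NULL)
    p <- compare_groups(c(sum(con$S), sum(con$L_analyzed)),
                        c(sum(rsx$S), sum(rsx$L_analyzed)), "chi-square")
    data.frame(group = grp,
               conserved_snp_per_bp = sum(con$S) / sum(con$L_analyzed),
               nonconserved_snp_per_bp = sum(rsx$S) / sum(rsx$L_analyzed),
               chi_square_p = p, stringsAsFactors = FALSE)
  }
  snp_contrasts <- do.call(rbind, Filter(Negate(is.null),
                                         lapply(c("cultivated", "wild"),
                                                contrast)))

  # reductions compare whole-locus fragments per class (the published
  # cultivated-vs-wild contrast is at the fragment level)
  reductions <- do.call(rbind, lapply(
    unique(stats::na.omit(sites$conservation_class)), function(cls) {
      pc <- mean(msub("cultivated", "locus", cls)$pi)
      pw <- mean(msub("wild", "locus", cls)$pi)
      data.frame(class = cls, pi_cultivated = pc, pi_wild = pw,
                 percent_reduction = round(percent_reduction(pc, pw)),
                 stringsAsFactors = FALSE)
    }))

  structure(list(diversity = div, table1 = t1, site_flank = site_flank,
                 table2_daf = table2, table3_tests = table3,
                 table4_duplex = table4, snp_contrasts = snp_contrasts,
                 reductions = reductions, log = log_lines,
                 settings = list(h_reps = h_reps, seed = seed,
                                 background_pi_per_kb = background_pi_per_kb)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", length(unique(x$diversity$locus)), "loci\n")
  cat("-- class summary (Table-1 layout) --\n"); print(x$table1)
  if (nrow(x$reductions)) {
    cat("-- diversity reduction in cultivated rice --\n"); print(x$reductions)
  }
  invisible(x)
}

#' Write an analysis report as a directory of TSV tables
#' @param report An [run_all()] result.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("diversity", "table1", "site_flank", "table2_daf",
            "table3_tests", "table4_duplex", "snp_contrasts", "reductions")
  for (tb in tabs) {
    utils::write.table(report[[tb]], file.path(outdir, paste0(tb, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$log, file.path(outdir, "filter_log.txt"))
  invisible(outdir)
}
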