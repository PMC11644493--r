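# synthetic_data: desk-scale emulation of the resequenced rice panel ----------
#
# Each locus receives one neutral coalescent genealogy over the full
# (panmictic) ingroup panel at the wild theta; domestication is emulated by
# thinning segregating sites within the cultivated subsample (a
# diversity-scaling bottleneck without multi-population coalescent
# machinery), purifying selection on conserved binding sites by rejecting
# mutations that land inside them with probability `constraint_c`, and
# sweeps at rice-specific sites by planting derived alleles at configured
# frequencies shared between cultivated and wild pools. Selection is
# emulated through the resulting polymorphism patterns, not fitness.

#' Configuration for the synthetic rice panel generator
#'
#' Defaults mirror the study panel: 16 indica, 17 temperate japonica,
#' 17 tropical japonica, 5 *O. nivara*, 19 *O. rufipogon* plus a single
#' outgroup accession; 26 loci of 716 bp each carrying one 21-22 nt binding
#' site (24 conserved, 2 rice-specific); wild diversity 5.19/kb; a 36%
#' bottleneck reduction in cultivated groups; conserved-site mutations
#' rejected with probability 0.95; three derived alleles planted per
#' rice-specific site at frequencies drawn from 0.8-0.95.
#'
#' @param pop_sizes Named integer vector of per-population haplotype counts;
#'   must contain an `outgroup` entry.
#' @param n_loci,locus_length Locus count and length (bp).
#' @param n_rice_specific How many loci carry a rice-specific site (the rest
#'   are conserved).
#' @param theta_wild_per_kb Wild-pool population mutation parameter per kb.
#' @param bottleneck_reduction Expected fractional diversity loss in
#'   cultivated groups (0-1).
#' @param constraint_c Probability that a mutation inside a conserved site
#'   is rejected (0-1).
#' @param site_widths Candidate binding-site widths.
#' @param sweep_n_alleles Derived alleles planted per rice-specific site.
#' @param sweep_daf_range Range the planted derived-allele frequencies are
#'   drawn from.
#' @param outgroup_divergence Per-site substitution rate on the outgroup
#'   lineage.
#' @param indels_per_locus Planted gap columns per rice-specific site
#'   (exercises the indel-exclusion rule; default 0).
#' @param seed Default seed used by [simulate_dataset()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(indica = 16L, temperate_japonica = 17L,
                                     tropical_japonica = 17L, nivara = 5L,
                                     rufipogon = 19L, outgroup = 1L),
                       n_loci = 26L, locus_length = 716L,
                       n_rice_specific = 2L,
                       theta_wild_per_kb = 5.19,
                       bottleneck_reduction = 0.36,
                       constraint_c = 0.95,
                       site_widths = c(21L, 22L),
                       sweep_n_alleles = 3L,
                       sweep_daf_range = c(0.8, 0.95),
                       outgroup_divergence = 0.005,
                       indels_per_locus = 0L,
                       seed = 1L) {
  stopifnot(all(pop_sizes >= 0), "outgroup" %in% names(pop_sizes),
            constraint_c >= 0, constraint_c <= 1,
            bottleneck_reduction >= 0, bottleneck_reduction < 1,
            all(sweep_daf_range > 0), all(sweep_daf_range < 1),
            n_rice_specific <= n_loci)
  structure(list(pop_sizes = pop_sizes, n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 n_rice_specific = as.integer(n_rice_specific),
                 theta_wild_per_kb = theta_wild_per_kb,
                 bottleneck_reduction = bottleneck_reduction,
                 constraint_c = constraint_c,
                 site_widths = as.integer(site_widths),
                 sweep_n_alleles = as.integer(sweep_n_alleles),
                 sweep_daf_range = sweep_daf_range,
                 outgroup_divergence = outgroup_divergence,
                 indels_per_locus = as.integer(indels_per_locus),
                 seed = seed),
            class = "sim_config")
}

.CULTIVATED <- c("indica", "temperate_japonica", "tropical_japonica")
.WILD <- c("nivara", "rufipogon")

.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Simulate a complete synthetic dataset with a truth ledger
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`); the output is reproducible
#'   byte-for-byte from `(config, seed)`.
#' @return Object of class `sim_dataset`: `alignments` (named list of
#'   [pop_alignment()]), `sites` (target-site data frame), `sample_sheet`,
#'   `mirnas` (named RNA vector, the reverse complements of the ancestral
#'   site sequences), and `truth` -- a per-locus ledger of the true theta,
#'   site coordinates, planted derived-allele frequencies, thinning applied
#'   and the seed, sufficient to recompute every expected statistic.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ps <- config$pop_sizes
  ingroup_pops <- setdiff(names(ps), "outgroup")
  n_in <- sum(ps[ingroup_pops])
  pop_of <- rep(ingroup_pops, ps[ingroup_pops])
  sample_id <- paste0(toupper(substr(pop_of, 1, 3)),
                      unlist(lapply(ps[ingroup_pops], seq_len)))
  sheet <- data.frame(
    sample_id = c(sample_id, "OUT1"),
    population = c(pop_of, "outgroup"),
    species = c(ifelse(pop_of %in% .CULTIVATED, "O. sativa",
                       paste("O.", pop_of)), "O. barthii"),
    stringsAsFactors = FALSE)
  cult_rows <- which(pop_of %in% .CULTIVATED)

  L <- config$locus_length
  theta_site <- config$theta_wild_per_kb / 1000
  classes <- c(rep("rice-specific", config$n_rice_specific),
               rep("conserved", config$n_loci - config$n_rice_specific))

  alignments <- list(); sites_rows <- list(); mirnas <- character(0)
  truth <- list()
  for (l in seq_len(config$n_loci)) {
    locus <- sprintf("locus%02d", l)
    cls <- classes[l]
    wid <- config$site_widths[sample.int(length(config$site_widths), 1L)]
    flank <- min(100L, (L - wid) %/% 3L)
    s0 <- sample.int(L - wid - 2L * flank + 1L, 1L) + flank - 1L
    site <- c(s0, s0 + wid)

    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # neutral genealogy over the whole ingroup panel at wild theta
    tr <- .coal_tree(n_in, keep_tips = TRUE)
    nmut <- stats::rpois(1L, theta_site * L / 2 * tr$total_len)
    pos <- sample.int(L, min(nmut, L))           # infinite sites on L columns
    br <- sample.int(length(tr$lens), length(pos), replace = TRUE,
                     prob = tr$lens)
    in_site <- pos > site[1] & pos <= site[2]
    if (cls == "conserved" && any(in_site)) {
      rej <- in_site & stats::runif(length(pos)) < config$constraint_c
      pos <- pos[!rej]; br <- br[!rej]
    }
    thinned <- stats::runif(length(pos)) < config$bottleneck_reduction

    mat <- matrix(rep(anc, each = n_in + 1L), nrow = n_in + 1L)
    n_seg <- 0L
    for (mj in seq_along(pos)) {
      carriers <- tr$members[[br[mj]]]
      if (thinned[mj]) carriers <- setdiff(carriers, cult_rows)
      if (!length(carriers)) next
      mat[carriers, pos[mj]] <- .other_base(anc[pos[mj]])
      n_seg <- n_seg + 1L
    }

    planted <- data.frame(col = integer(), daf = numeric(),
                          carriers = integer())
    if (cls == "rice-specific" && config$sweep_n_alleles > 0L) {
      site_cols <- (site[1] + 1L):site[2]
      cols <- sample(site_cols, min(config$sweep_n_alleles, wid))
      for (cc in cols) {
        daf <- stats::runif(1L, config$sweep_daf_range[1],
                            config$sweep_daf_range[2])
        ncar <- max(1L, round(daf * n_in))
        carriers <- sample.int(n_in, ncar)
        mat[carriers, cc] <- .other_base(anc[cc])
        planted <- rbind(planted, data.frame(col = cc - 1L,
                                             daf = ncar / n_in,
                                             carriers = ncar))
      }
      if (config$indels_per_locus > 0L) {
        gcols <- sample(site_cols, min(config$indels_per_locus, wid))
        for (gc in gcols) {
          ng <- sample.int(max(1L, n_in %/% 8L), 1L)
          mat[sample.int(n_in, ng), gc] <- "-"
        }
      }
    }

    # outgroup lineage: substitutions dropped on the ancestral sequence
    og <- anc
    ndiv <- stats::rpois(1L, config$outgroup_divergence * L)
    dpos <- sample.int(L, min(ndiv, L))
    for (dp in dpos) og[dp] <- .other_base(anc[dp])
    mat[n_in + 1L, ] <- og

    seqs <- apply(mat, 1L, paste, collapse = "")
    alignments[[locus]] <- pop_alignment(
      seqs, sample_id = sheet$sample_id, population = sheet$population,
      locus_id = locus)
    mirna_id <- paste0("osa-miRsim-", locus)
    mirnas[mirna_id] <- reverse_complement_rna(
      paste(anc[(site[1] + 1L):site[2]], collapse = ""))
    sites_rows[[locus]] <- data.frame(
      locus = locus, start = site[1], end = site[2], mirna_id = mirna_id,
      conservation_class = cls, region_class = "unknown",
      stringsAsFactors = FALSE)
    truth[[locus]] <- list(theta_per_site = theta_site, site = site,
                           class = cls, planted = planted,
                           n_mutations = length(pos),
                           n_thinned = sum(thinned),
                           outgroup_substitutions = length(dpos))
  }
  structure(list(alignments = alignments,
                 sites = do.call(rbind, c(sites_rows,
                                          list(make.row.names = FALSE))),
                 sample_sheet = sheet, mirnas = mirnas,
                 truth = c(truth, list(seed = seed, config = config))),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", length(x$alignments), "loci,",
      nrow(x$sample_sheet), "samples,", nrow(x$sites), "binding sites\n")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits one FASTA per locus, `sites.tsv`, `samples.tsv`, `mirnas.fa` and a
#' structured `truth.txt` ledger.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (locus in names(dataset$alignments)) {
    write_alignment(dataset$alignments[[locus]],
                    file.path(outdir, paste0(locus, ".fa")))
  }
  write_sites(dataset$sites, file.path(outdir, "sites.tsv"))
  write_sample_sheet(dataset$sample_sheet, file.path(outdir, "samples.tsv"))
  writeLines(as.vector(rbind(paste0(">", names(dataset$mirnas)),
                             dataset$mirnas)),
             file.path(outdir, "mirnas.fa"))
  utils::capture.output(utils::str(dataset$truth, list.len = 1000),
                        file = file.path(outdir, "truth.txt"))
  invisible(outdir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Directory path.
#' @return A list with `alignments`, `sites`, `sample_sheet`, `mirnas`
#'   (class `sim_dataset`, without the truth ledger).
#' @export
read_dataset <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  fas <- sort(list.files(dir, pattern = "^locus.*\\.fa$", full.names = TRUE))
  alignments <- lapply(fas, read_alignment, sample_sheet = sheet)
  names(alignments) <- vapply(alignments, `[[`, character(1), "locus_id")
  lens <- vapply(alignments, alignment_length, integer(1))
  structure(list(alignments = alignments,
                 sites = read_sites(file.path(dir, "sites.tsv"), lens),
                 sample_sheet = sheet,
                 mirnas = read_mirnas(file.path(dir, "mirnas.fa")),
                 truth = NULL),
            class = "sim_dataset")
}

#' Canned deterministic fixtures for unit tests and examples
#'
#' `"toy_pi"`: 4 haplotypes x 10 bp with two segregating sites
#' (`pi = 7/60`); `"monomorphic"`: 4 identical haplotypes; `"sweep_site"`:
#' 4 haplotypes plus outgroup with one derived allele at frequency 0.75
#' inside an annotated site (attributes `site` and `truth_daf`).
#'
#' @param name Fixture name.
#' @return A [pop_alignment()] (byte-stable across runs).
#' @export
make_fixture <- function(name) {
  switch(name,
    toy_pi = pop_alignment(
      c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT", "AAAAAAAAAA"),
      sample_id = paste0("s", 1:4), population = "pop1",
      locus_id = "toy_pi"),
    monomorphic = pop_alignment(
      rep("ACGTACGTACGTACGTACGT", 4),
      sample_id = paste0("s", 1:4), population = "pop1",
      locus_id = "monomorphic"),
    sweep_site = {
      aln <- pop_alignment(
        c("ACGTACGTACGTACGTACGT",
          "ACGTACGAACGTACGTACGT",
          "ACGTACGAACGTACGTACGT",
          "ACGTACGAACGTACGTACGT",
          "ACGTACGTACGTACGTACGT"),
        sample_id = c(paste0("s", 1:4), "og"),
        population = c(rep("pop1", 4), "outgroup"),
        locus_id = "sweep_site")
      attr(aln, "site") <- c(4L, 12L)
      attr(aln, "truth_daf") <- 0.75
      aln
    },
    stop("registry error: unknown fixture '", name, "'"))
}
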