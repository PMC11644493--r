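# seqio: population alignments, target-site tables, sample sheets -------------
#
# Coordinates are 0-based half-open everywhere (alignment columns and the
# BED-like site table share the convention), which removes off-by-one drift
# between annotation and slicing.

#' Construct a population alignment
#'
#' A phased haplotype alignment with a population label per haplotype. All
#' sequences must have identical length; the alphabet is `A,C,G,T,N,-` after
#' normalization (`U` is folded into `T` on input). At most one label is the
#' designated outgroup (by convention `"outgroup"`, overridable in downstream
#' calls).
#'
#' @param sequences Character vector of aligned haplotype sequences.
#' @param sample_id Character vector of unique haplotype identifiers.
#' @param population Character vector of population labels (recycled if
#'   length 1).
#' @param locus_id Single locus identifier.
#' @return An object of class `pop_alignment` with fields `locus_id`, `mat`
#'   (character matrix, haplotypes x columns), `sample_id`, `population`.
#' @export
pop_alignment <- function(sequences, sample_id = NULL, population = "ingroup",
                          locus_id = "locus") {
  sequences <- vapply(sequences, .norm_dna, character(1), USE.NAMES = FALSE)
  n <- length(sequences)
  if (n == 0L) stop("alignment error: no sequences")
  if (is.null(sample_id)) sample_id <- paste0("hap", seq_len(n))
  if (anyDuplicated(sample_id)) stop("metadata error: duplicated sample ids")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  population <- rep_len(as.character(population), n)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) stop("alignment error: invalid characters in sequence(s) ",
                     paste(sample_id[bad], collapse = ", "))
  mat <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                nrow = n, byrow = TRUE,
                dimnames = list(sample_id, NULL))
  structure(list(locus_id = locus_id, mat = mat,
                 sample_id = sample_id, population = population),
            class = "pop_alignment")
}

#' @export
print.pop_alignment <- function(x, ...) {
  cat("pop_alignment '", x$locus_id, "': ", nrow(x$mat), " haplotypes x ",
      ncol(x$mat), " columns\n", sep = "")
  tab <- table(x$population)
  cat("  populations:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / alignment length
#' @param aln A `pop_alignment`.
#' @return Integer count.
#' @export
n_haplotypes <- function(aln) nrow(aln$mat)

#' @rdname n_haplotypes
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Haplotype sequences as strings
#' @param aln A `pop_alignment`.
#' @return Named character vector.
#' @export
alignment_sequences <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$sample_id)
}

#' Read a population alignment from FASTA plus a sample sheet
#'
#' Every FASTA record id (first whitespace-delimited token) must resolve in
#' the sample sheet; the sheet attaches population labels.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param sample_sheet Data frame with columns `sample_id`, `population`
#'   (optionally `species`), or a path to such a TSV.
#' @param locus_id Locus identifier; defaults to the FASTA file stem.
#' @return A [pop_alignment()].
#' @export
read_alignment <- function(fasta_path, sample_sheet,
                           locus_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  recs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  missing <- setdiff(ids, sample_sheet$sample_id)
  if (length(missing)) {
    stop("metadata error: sample id(s) not in sample sheet: ",
         paste(missing, collapse = ", "))
  }
  pop <- sample_sheet$population[match(ids, sample_sheet$sample_id)]
  pop_alignment(seqs, sample_id = ids, population = pop, locus_id = locus_id)
}

#' Write a population alignment as FASTA
#'
#' Unwrapped records, one per haplotype, in alignment order;
#' `write_alignment(read_alignment(x, sheet), f)` round-trips byte-identically
#' for files produced by this writer.
#'
#' @param aln A `pop_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- alignment_sequences(aln)
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Extract a column interval from an alignment
#'
#' @param aln A `pop_alignment`.
#' @param start,end 0-based half-open column coordinates.
#' @return A `pop_alignment` of length `end - start` with haplotype order and
#'   labels preserved.
#' @export
extract_region <- function(aln, start, end) {
  L <- ncol(aln$mat)
  if (!(.is_count(start) && .is_count(end)) || start >= end || end > L) {
    stop("coordinate error: need 0 <= start < end <= ", L,
         " (got [", start, ", ", end, "))")
  }
  out <- aln
  out$mat <- aln$mat[, (start + 1L):end, drop = FALSE]
  out
}

#' Read / write a sample sheet
#'
#' TSV with header columns `sample_id`, `population`, and optionally
#' `species`. Sample ids must be unique.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(df))) {
    stop("metadata error: sample sheet must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("metadata error: duplicated sample ids")
  df
}

#' @rdname read_sample_sheet
#' @param sheet Data frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-site table
#'
#' BED-like TSV with columns `locus`, `start`, `end`, `mirna_id`,
#' `conservation_class` and optionally `region_class`; 0-based half-open
#' coordinates. A header line is detected by a first field equal to `locus`.
#'
#' @param path File path.
#' @param locus_lengths Optional named vector of alignment lengths used to
#'   validate coordinates.
#' @return Data frame of target sites (empty for an empty file).
#' @export
read_sites <- function(path, locus_lengths = NULL) {
  cols <- c("locus", "start", "end", "mirna_id", "conservation_class",
            "region_class")
  first <- readLines(path, n = 1L)
  empty <- length(first) == 0L
  has_header <- !empty && identical(strsplit(first, "\t")[[1]][1], "locus")
  if (empty || (has_header && length(readLines(path)) == 1L)) {
    df <- as.data.frame(stats::setNames(
      list(character(), integer(), integer(), character(), character(),
           character()), cols))
    return(df)
  }
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 5L) stop("site table error: need >= 5 columns")
    names(df)[1:min(6L, ncol(df))] <- cols[1:min(6L, ncol(df))]
  }
  if (!"region_class" %in% names(df)) df$region_class <- "unknown"
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad)) {
    stop("site record error: start >= end (or negative) on line(s) ",
         paste(bad + has_header, collapse = ", "))
  }
  if (!is.null(locus_lengths)) {
    over <- which(df$locus %in% names(locus_lengths) &
                    df$end > locus_lengths[df$locus])
    if (length(over)) {
      stop("site record error: end exceeds locus length on line(s) ",
           paste(over + has_header, collapse = ", "))
    }
  }
  df[, cols]
}

#' @rdname read_sites
#' @param sites Site data frame to write.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of RNA sequences (T folded into U).
#' @export
read_mirnas <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  stats::setNames(vapply(as.character(recs), .norm_rna, character(1),
                         USE.NAMES = FALSE),
                  sub("\\s.*$", "", names(recs)))
}
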