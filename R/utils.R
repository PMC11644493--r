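# internal helpers shared across modules

#' Harmonic number
#'
#' `a_k = sum_{j=1}^{k} 1/j`, the constant appearing in Watterson's estimator
#' (`theta_W = S / (a_{n-1} L)`) and in the expected number of segregating
#' sites under the neutral coalescent.
#'
#' @param k Non-negative integer.
#' @return `sum(1/(1:k))`; 0 for `k = 0`.
#' @export
harmonic_number <- function(k) {
  stopifnot(length(k) == 1L, is.finite(k), k >= 0)
  if (k < 1) return(0)
  sum(1 / seq_len(k))
}

# uppercase and collapse U -> T (internal DNA alphabet)
.norm_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# uppercase and collapse T -> U (miRNA-facing RNA alphabet)
.norm_rna <- function(x) chartr("t", "U", chartr("T", "U", toupper(x)))

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "N", `-` = "-")
.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse complement of an RNA sequence
#' @param x Single RNA/DNA string (T and U treated alike).
#' @return Reverse complement as an RNA string.
#' @export
reverse_complement_rna <- function(x) {
  ch <- rev(strsplit(.norm_rna(x), "")[[1]])
  paste(.RNA_COMP[ch], collapse = "")
}

.chars <- function(x) strsplit(x, "")[[1]]

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

# %||% in the rlang sense, for optional config entries
`%||%` <- function(a, b) if (is.null(a)) b else a
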