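# target_scan: empirical plant miRNA target filter -----------------------------
#
# A candidate site is aligned antiparallel and end-to-end against the mature
# miRNA (at most one indel), each miRNA position is assigned a pairing state,
# and the profile is pushed through the positional rule filter used for
# empirical plant target validation:
#   (1) no mismatch at miRNA positions 10 and 11;
#   (2) no more than one mismatch at positions 2-12;
#   (3) no more than two consecutive mismatches downstream of position 13;
#   (4) fewer than 5 mismatches in total;
# with G:U wobbles treated as mismatches for the rules and a numeric score
# cutoff of 3 (mismatch 1.0, G:U 0.5, gap 1.0).

.pair_state <- function(a, b) {
  # a: miRNA base (RNA), b: target base (RNA), antiparallel contact
  wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  if (wc) return("match")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("GU")
  "mismatch"
}

.STATE_PENALTY <- c(match = 0, GU = 0.5, mismatch = 1, gap = 1)

#' Pairing profile of a candidate target site against a miRNA
#'
#' Aligns the site antiparallel and end-to-end to the miRNA, allowing at most
#' one indel (of length up to 2, reconciling the length difference). Among
#' equal-penalty placements the profile with the gap closest to the miRNA
#' 3' end is chosen (the 3' region tolerates distortion in plant pairing).
#'
#' States are indexed by miRNA position `p = 1..n` from the miRNA 5' end.
#' When the site is shorter than the miRNA, the skipped miRNA positions carry
#' state `"gap"`; when longer, the extra (bulged) site bases are recorded in
#' `site_bulge` and penalized but occupy no miRNA position.
#'
#' @param mirna_seq Mature miRNA, 5'->3' (RNA or DNA letters).
#' @param site_seq Candidate site, 5'->3' on the transcript; length within
#'   `n +/- 2` of the miRNA length `n`.
#' @param mirna_id Optional identifier stored in the profile.
#' @return Object of class `pairing_profile`: list with `states` (length
#'   `n`), `n`, `m`, `n_bulge`, `penalty`, the normalized sequences and the
#'   gap placement.
#' @export
pair_profile <- function(mirna_seq, site_seq, mirna_id = NA_character_) {
  mi <- .chars(.norm_rna(mirna_seq))
  si <- .chars(.norm_rna(site_seq))
  n <- length(mi); m <- length(si)
  if (n == 0L || m == 0L) stop("scan error: empty sequence")
  if (abs(m - n) > 2L) {
    stop("scan error: site length ", m, " outside miRNA length ", n, " +/- 2")
  }
  sr <- rev(si)  # sr[k] faces miRNA position k in the ungapped register
  d <- m - n

  score_states <- function(states) sum(.STATE_PENALTY[states])

  if (d == 0L) {
    states <- vapply(seq_len(n), function(p) .pair_state(mi[p], sr[p]),
                     character(1))
    best <- list(states = states, gap_at = integer(0), bulge = character(0),
                 penalty = score_states(states))
  } else if (d < 0L) {
    g <- -d  # site shorter: g miRNA positions unpaired (one gap of length g)
    cand <- lapply(seq_len(n - g + 1L), function(j) {
      states <- character(n)
      gap_pos <- j:(j + g - 1L)
      states[gap_pos] <- "gap"
      k <- 0L
      for (p in seq_len(n)[-gap_pos]) {
        k <- k + 1L
        states[p] <- .pair_state(mi[p], sr[k])
      }
      list(states = states, gap_at = gap_pos, bulge = character(0),
           penalty = score_states(states))
    })
    pen <- vapply(cand, `[[`, numeric(1), "penalty")
    # tie-break: gap closest to the miRNA 3' end (largest start)
    best <- cand[[max(which(pen == min(pen)))]]
  } else {
    g <- d  # site longer: g site bases bulged between miRNA positions j, j+1
    cand <- lapply(0:n, function(j) {
      states <- vapply(seq_len(n), function(p) {
        .pair_state(mi[p], if (p <= j) sr[p] else sr[p + g])
      }, character(1))
      list(states = states, gap_at = integer(0),
           bulge = sr[(j + 1L):(j + g)], bulge_after = j,
           penalty = score_states(states) + g * .STATE_PENALTY[["gap"]])
    })
    pen <- vapply(cand, `[[`, numeric(1), "penalty")
    best <- cand[[max(which(pen == min(pen)))]]
  }

  structure(list(mirna_id = mirna_id,
                 mirna = paste(mi, collapse = ""),
                 site = paste(si, collapse = ""),
                 states = best$states,
                 gap_at = best$gap_at,
                 site_bulge = best$bulge,
                 bulge_after = best$bulge_after %||% NA_integer_,
                 n = n, m = m,
                 n_bulge = length(best$bulge),
                 penalty = unname(best$penalty)),
            class = "pairing_profile")
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat("pairing_profile: n =", x$n, "m =", x$m, "penalty =", x$penalty, "\n")
  sym <- c(match = "|", GU = "o", mismatch = "x", gap = "-")
  cat("  5'-", x$mirna, "-3' (miRNA)\n     ",
      paste(sym[x$states], collapse = ""), "\n", sep = "")
  invisible(x)
}

# coerce either a pairing_profile or a bare state vector for rule evaluation
.as_states <- function(profile) {
  if (inherits(profile, "pairing_profile")) profile$states
  else if (is.character(profile) &&
           all(profile %in% names(.STATE_PENALTY))) profile
  else stop("not a pairing profile or state vector")
}

#' Apply the positional target filter to a pairing profile
#'
#' Rules evaluated with G:U and gap states counted as full mismatches:
#' `pos10-11` (no mismatch at positions 10-11), `max1-pos2-12` (at most one
#' mismatch at positions 2-12), `max2-consec-post13` (no more than two
#' consecutive mismatches downstream of position 13, inclusive by default)
#' and `max4-total` (fewer than 5 mismatches overall, bulged site bases
#' included). The numeric score (mismatch 1, G:U 0.5, gap 1) must in addition
#' not exceed `score_cutoff`.
#'
#' @param profile A [pair_profile()] result, or a character vector of states
#'   in `match/GU/mismatch/gap` (then `n_bulge` may be given separately).
#' @param score_cutoff Maximum score still accepted (default 3).
#' @param downstream_inclusive Whether "downstream of position 13" includes
#'   position 13 (default `TRUE`).
#' @param n_bulge Bulged site bases when `profile` is a bare state vector.
#' @return Object of class `filter_verdict`: `passed`, `score`,
#'   `violated_rules` (empty iff all positional rules hold and score is
#'   within the cutoff).
#' @export
evaluate_filter <- function(profile, score_cutoff = 3,
                            downstream_inclusive = TRUE, n_bulge = NULL) {
  states <- .as_states(profile)
  if (is.null(n_bulge)) {
    n_bulge <- if (inherits(profile, "pairing_profile")) profile$n_bulge else 0L
  }
  n <- length(states)
  mm <- which(states != "match")        # rule mismatches: mismatch, GU, gap
  total_mm <- length(mm) + n_bulge
  score <- sum(.STATE_PENALTY[states]) + n_bulge * .STATE_PENALTY[["gap"]]

  violated <- character(0)
  if (any(mm %in% c(10L, 11L))) violated <- c(violated, "pos10-11")
  if (sum(mm >= 2L & mm <= 12L) > 1L) violated <- c(violated, "max1-pos2-12")
  lo <- if (downstream_inclusive) 13L else 14L
  down <- mm[mm >= lo]
  if (length(down) >= 3L) {
    runs <- rle(diff(down) == 1L)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L else 1L
    if (max_run > 2L) violated <- c(violated, "max2-consec-post13")
  }
  if (total_mm >= 5L) violated <- c(violated, "max4-total")
  if (score > score_cutoff) violated <- c(violated, "score-cutoff")

  structure(list(passed = length(violated) == 0L,
                 score = unname(score),
                 violated_rules = violated,
                 total_mismatches = total_mm),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat("filter_verdict:", if (x$passed) "PASS" else "FAIL",
      "score =", x$score,
      if (!x$passed) paste0("[", paste(x$violated_rules, collapse = ", "), "]"),
      "\n")
  invisible(x)
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Every window of width `n - 1`, `n` and `n + 1` (miRNA length `n`) is
#' profiled and filtered; passing windows are returned sorted by score then
#' start coordinate. Overlapping passes are all reported.
#'
#' @param mirna_seq Mature miRNA 5'->3'.
#' @param transcript_seq Transcript sequence (DNA or RNA letters).
#' @param mirna_id Identifier copied into the result.
#' @param ... Passed to [evaluate_filter()].
#' @return Data frame with columns `start`, `end` (0-based half-open
#'   transcript coordinates), `mirna_id`, `score`, `passed`,
#'   `violated_rules`, `site`.
#' @export
scan_transcript <- function(mirna_seq, transcript_seq,
                            mirna_id = NA_character_, ...) {
  tx <- .norm_rna(transcript_seq)
  Lt <- nchar(tx)
  n <- nchar(.norm_rna(mirna_seq))
  if (Lt < n - 1L) stop("scan error: transcript shorter than miRNA - 1")
  rows <- list()
  for (w in (n - 1L):(n + 1L)) {
    if (w < 1L || w > Lt) next
    for (s in 0:(Lt - w)) {
      site <- substr(tx, s + 1L, s + w)
      prof <- pair_profile(mirna_seq, site, mirna_id = mirna_id)
      verdict <- evaluate_filter(prof, ...)
      if (verdict$passed) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + w, mirna_id = mirna_id,
          score = verdict$score, passed = TRUE,
          violated_rules = "", site = site,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      mirna_id = character(), score = numeric(),
                      passed = logical(), violated_rules = character(),
                      site = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
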