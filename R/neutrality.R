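# neutrality: Fay & Wu's H and the ML multilocus HKA test ---------------------

#' Fay and Wu's H from a polarized site-frequency spectrum
#'
#' `theta_pi = sum_i 2 xi_i i (n - i) / (n (n - 1))`,
#' `theta_H  = sum_i 2 xi_i i^2 / (n (n - 1))`, `H = theta_pi - theta_H`
#' (unstandardized; per locus, not per site). An excess of high-frequency
#' derived alleles, the footprint of hitchhiking, drives `H` negative.
#'
#' @param sfs A [polarized_sfs()].
#' @return Object of class `h_statistic` with `theta_pi`, `theta_H`, `H`,
#'   `n`, `S` (`H = 0` for monomorphic data).
#' @export
fay_wu_H <- function(sfs) {
  stopifnot(inherits(sfs, "polarized_sfs"))
  n <- sfs$n
  i <- seq_len(n - 1L)
  xi <- as.numeric(sfs$xi)
  denom <- n * (n - 1)
  theta_pi <- sum(2 * xi * i * (n - i)) / denom
  theta_H <- sum(2 * xi * i^2) / denom
  structure(list(theta_pi = theta_pi, theta_H = theta_H,
                 H = theta_pi - theta_H, n = n, S = sum(xi),
                 p_value = NA_real_, R = NA_integer_),
            class = "h_statistic")
}

#' @export
print.h_statistic <- function(x, ...) {
  cat(sprintf("Fay & Wu's H: theta_pi=%.4f  theta_H=%.4f  H=%.4f",
              x$theta_pi, x$theta_H, x$H))
  if (!is.na(x$p_value)) cat(sprintf("  p=%.4g (R=%d)", x$p_value, x$R))
  cat("\n")
  invisible(x)
}

#' Fay and Wu's H test with a fixed-S coalescent null
#'
#' The null distribution is simulated with [simulate_coalescent()] in
#' fixed-S mode at the observed `n` and `S` (robust to misspecification of
#' theta). The test is one-tailed toward negative `H`:
#' `p = (1 + #{H_sim <= H_obs}) / (R + 1)`.
#'
#' @param sfs A [polarized_sfs()] with at least one polarized site.
#' @param R Null replicates.
#' @param seed Optional seed.
#' @return An `h_statistic` with `p_value` filled in (`NA` and a warning
#'   when `S = 0`).
#' @export
h_test <- function(sfs, R = 10000L, seed = NULL) {
  hs <- fay_wu_H(sfs)
  if (hs$S == 0L) {
    warning("S = 0: Fay & Wu's H p-value undefined")
    return(hs)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- hs$n
  denom <- n * (n - 1)
  h_null <- vapply(seq_len(R), function(r) {
    i <- .sim_derived_counts(n, S = hs$S)
    sum(2 * i * (n - i) - 2 * i^2) / denom
  }, numeric(1))
  hs$p_value <- (1 + sum(h_null <= hs$H)) / (R + 1)
  hs$R <- as.integer(R)
  hs
}

#' Assemble a multilocus HKA input table
#'
#' @param locus Character locus ids.
#' @param S Segregating sites per locus.
#' @param D Net differences to the outgroup per locus.
#' @param n Sample size per locus.
#' @param L Sequence length per locus.
#' @param selected Logical: candidate loci whose selection parameter `k` is
#'   free; reference loci have `k = 1`.
#' @return Data frame of class `hka_data`.
#' @export
hka_data <- function(locus, S, D, n, L = NA_integer_, selected = FALSE) {
  df <- data.frame(locus = as.character(locus), S = as.numeric(S),
                   D = as.numeric(D), n = as.integer(n), L = L,
                   selected = rep_len(as.logical(selected), length(locus)),
                   stringsAsFactors = FALSE)
  if (any(df$S < 0) || any(df$D < 0)) stop("counts must be non-negative")
  if (anyDuplicated(df$locus)) stop("duplicated locus ids")
  class(df) <- c("hka_data", "data.frame")
  df
}

# Poisson log pmf with the 0*log(0) = 0 convention
.lpois <- function(x, mu) {
  ifelse(mu == 0,
         ifelse(x == 0, 0, -Inf),
         x * log(mu) - mu - lgamma(x + 1))
}

#' Maximum-likelihood multilocus HKA test
#'
#' Wright-Charlesworth style Poisson approximation: per locus,
#' `S_i ~ Poisson(k_i theta_i a_{n_i - 1})` and
#' `D_i ~ Poisson(theta_i (T + 1))`, with `k_i = 1` at reference loci and
#' free at selected loci. `T + 1` is the divergence mean in coalescent
#' units: the outgroup lineage of length `T` plus the expected contribution
#' of the ancestral coalescent with a single outgroup sequence. The
#' selection parameter scales polymorphism only, which keeps `k` and
#' `theta` separately identifiable.
#'
#' Fitting is by profile likelihood: given `T`, each `theta_i` has a
#' closed-form MLE (and each selected locus is saturated), and the profile
#' log-likelihood is concave in `log(T + 1)`, so a one-dimensional
#' deterministic maximization is exact. The likelihood-ratio statistic
#' `2 (logL_alt - logL_null)` is referred to a chi-square with one degree
#' of freedom per selected locus.
#'
#' @param data An [hka_data()] table (or data frame with the same columns);
#'   at least two loci, at least one of them a reference locus.
#' @param tol Relative tolerance of the 1-D maximization.
#' @return Object of class `hka_fit`: `theta` (named per-locus estimates),
#'   `T`, `k` (named, selected loci), `logL_null`, `logL_alt`, `LRT`, `df`,
#'   `p_value`, `boundary` (selected loci whose `k` MLE sits on a boundary
#'   because `S = 0` or `D = 0`).
#' @export
mlhka_fit <- function(data, tol = 1e-10) {
  stopifnot(is.data.frame(data))
  need <- c("locus", "S", "D", "n", "selected")
  if (!all(need %in% names(data))) {
    stop("hka data must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 2L) stop("need at least 2 loci")
  if (all(data$selected)) stop("unidentifiable: all loci selected")
  a <- vapply(data$n - 1L, harmonic_number, numeric(1))
  sel <- data$selected

  # log-likelihood profile in v = log(T + 1); theta profiled out
  loglik_profile <- function(v, constrained) {
    u <- exp(v)                       # u = T + 1 > 0
    ll <- 0
    for (i in seq_len(nrow(data))) {
      Si <- data$S[i]; Di <- data$D[i]
      if (constrained || !sel[i]) {
        th <- (Si + Di) / (a[i] + u)
        ll <- ll + .lpois(Si, th * a[i]) + .lpois(Di, th * u)
      } else {
        # saturated: mu = S, nu = D attainable (boundary cases included)
        ll <- ll + .lpois(Si, Si) + .lpois(Di, Di)
      }
    }
    ll
  }

  fit_T <- function(constrained) {
    opt <- stats::optimize(loglik_profile, interval = c(-20, 20),
                           constrained = constrained, maximum = TRUE,
                           tol = tol)
    list(v = opt$maximum, logL = opt$objective)
  }
  null_fit <- fit_T(constrained = TRUE)
  alt_fit <- fit_T(constrained = FALSE)
  # the null is nested in the alternative; guard the invariant against
  # 1-D optimizer tolerance at machine precision
  alt_fit$logL <- max(alt_fit$logL, null_fit$logL)

  u_alt <- exp(alt_fit$v)
  T_hat <- u_alt - 1
  theta <- numeric(nrow(data)); k <- rep(NA_real_, nrow(data))
  boundary <- character(0)
  for (i in seq_len(nrow(data))) {
    Si <- data$S[i]; Di <- data$D[i]
    if (!sel[i]) {
      theta[i] <- (Si + Di) / (a[i] + u_alt)
      k[i] <- 1
    } else {
      theta[i] <- Di / u_alt
      if (Di > 0 && Si > 0) {
        k[i] <- Si * u_alt / (Di * a[i])
      } else if (Si == 0) {
        k[i] <- 0; boundary <- c(boundary, data$locus[i])
      } else {
        k[i] <- Inf; boundary <- c(boundary, data$locus[i])
      }
    }
  }
  lrt <- max(0, 2 * (alt_fit$logL - null_fit$logL))
  df <- sum(sel)
  structure(list(theta = stats::setNames(theta, data$locus),
                 T = T_hat,
                 k = stats::setNames(k[sel], data$locus[sel]),
                 logL_null = null_fit$logL, logL_alt = alt_fit$logL,
                 LRT = lrt, df = df,
                 p_value = stats::pchisq(lrt, df = df, lower.tail = FALSE),
                 boundary = boundary),
            class = "hka_fit")
}

#' @export
print.hka_fit <- function(x, ...) {
  cat(sprintf("mlhka_fit: T=%.3f  LRT=%.3f (df=%d)  p=%.4g\n",
              x$T, x$LRT, x$df, x$p_value))
  if (length(x$k)) {
    cat("  k-hat:", paste(names(x$k), sprintf("%.3f", x$k), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}
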