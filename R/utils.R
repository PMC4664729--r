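# Shared vocabularies and small numeric primitives.

FAMILIES <- c("EA", "AE")
SAMPLE_TYPES <- c("larva", "guard", "brain")
TRAIT_CLASSES <- c("defense", "reproduction", "foraging")

# The nine bias categories: one per (state_EA, state_AE) pair of M/P/N states.
BIAS_CATEGORIES <- c(
  "maternal_both", "paternal_both",
  "ea_maternal_only", "ae_maternal_only",
  "ea_paternal_only", "ae_paternal_only",
  "european_allele", "africanized_allele",
  "unbiased"
)
MULTI <- "MULTI"

#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution parameterised by the mean
#' success fraction `mu` and the intra-class correlation `rho` (the
#' overdispersion of replicate allele counts relative to binomial sampling).
#' `rho = 0` reduces exactly to the binomial distribution.
#'
#' @param x Number of successes (vectorised).
#' @param size Number of trials.
#' @param mu Mean fraction in (0, 1).
#' @param rho Intra-class correlation in `[0, 1)`.
#' @param log Return log density?
#' @return Numeric vector of (log) probabilities.
#' @export
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  stopifnot(rho >= 0, rho < 1, mu >= 0, mu <= 1)
  if (rho == 0 || mu == 0 || mu == 1) {
    return(stats::dbinom(x, size, mu, log = log))
  }
  theta <- (1 - rho) / rho
  a <- mu * theta
  b <- (1 - mu) * theta
  lp <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  lp[x < 0 | x > size | x != round(x)] <- -Inf
  if (log) lp else exp(lp)
}

# Exact two-sided binomial p-value with the probability-mass ordering used
# throughout: sum of P(X = k) over all k whose probability does not exceed
# that of the observed count (within a small relative tolerance guarding
# against floating-point ties).
binom_two_sided_p <- function(m, n, prob = 0.5) {
  if (n == 0L) return(NA_real_)
  d <- stats::dbinom(0:n, n, prob)
  min(1, sum(d[d <= d[m + 1L] * (1 + 1e-7)]))
}

# Validate a value against a closed vocabulary, reporting offending entries
# (and 1-based data line numbers when `lines` is given).
check_vocab <- function(x, vocab, what, lines = NULL) {
  bad <- !(x %in% vocab)
  if (any(bad)) {
    where <- if (is.null(lines)) which(bad) else lines[bad]
    stop(sprintf(
      "invalid %s %s at line %s (allowed: %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(where, 5), collapse = ", "),
      paste(vocab, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

geometric_mean <- function(x) exp(mean(log(x)))
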