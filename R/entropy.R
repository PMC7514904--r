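#' @keywords internal
#' @noRd
.check_entropy_args <- function(x, m, r) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("`x` must be a numeric sequence of finite values", call. = FALSE)
  if (length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a single positive integer", call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (length(x) < m + 2)
    stop(sprintf("sequence too short: need N >= m + 2 (N = %d, m = %d)",
                 length(x), as.integer(m)), call. = FALSE)
  invisible(TRUE)
}

# Pairwise Chebyshev distance matrix between all length-m templates of x
# (templates 1 .. N - m + 1). O(N^2 m) time and O(N^2) memory; windows here
# are at most a few hundred samples.
.template_dists <- function(x, m) {
  nt <- length(x) - m + 1L
  d <- matrix(0, nt, nt)
  for (k in seq_len(m) - 1L) {
    xk <- x[(1L + k):(nt + k)]
    d <- pmax(d, abs(outer(xk, xk, "-")))
  }
  d
}

# Same, after removing each template's own mean (the fuzzy-entropy baseline).
.template_dists_centered <- function(x, m) {
  nt <- length(x) - m + 1L
  tm <- matrix(0, nt, m)
  for (k in seq_len(m)) tm[, k] <- x[k:(nt + k - 1L)]
  tm <- tm - rowMeans(tm)
  d <- matrix(0, nt, nt)
  for (k in seq_len(m)) d <- pmax(d, abs(outer(tm[, k], tm[, k], "-")))
  d
}

# Tiny negative results are floating-point artefacts of the phi difference;
# genuinely negative ApEn can occur and is returned untouched.
.clamp_zero <- function(v, tol = 1e-12) {
  if (!is.na(v) && v < 0 && abs(v) < tol) 0 else v
}

#' Chebyshev distance between two embedded templates
#'
#' Distance between the length-`m` templates of `x` starting at positions
#' `i` and `j`: the maximum absolute difference over aligned components.
#' This is the template distance underlying all three entropy measures.
#'
#' @param x Numeric sequence.
#' @param i,j 1-based template start indices, each in `1:(length(x) - m + 1)`.
#' @param m Template (embedding) length.
#' @return A single nonnegative number; zero iff the templates are identical.
#' @examples
#' template_distance(c(3, 9, 1, 1), 1, 3, m = 2)  # max(|3-1|, |9-1|) = 8
#' @export
template_distance <- function(x, i, j, m) {
  n <- length(x)
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer", call. = FALSE)
  nt <- n - m + 1L
  if (i < 1 || j < 1 || i > nt || j > nt)
    stop(sprintf("template index out of range: need 1 <= i, j <= %d", nt),
         call. = FALSE)
  max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
}

#' Approximate Entropy
#'
#' Regularity statistic of Pincus: templates of length `m` are compared by
#' Chebyshev distance, matches are counted with the closed inequality
#' `d <= r` *including* the self-match (which guarantees every count is
#' positive), and the statistic is the difference
#' `phi^m(r) - phi^(m+1)(r)` of the mean log match frequencies. Lower values
#' indicate a more regular sequence; a constant sequence scores exactly 0.
#'
#' `r` is an absolute tolerance in the units of `x`. For sequences drawn
#' from the odd room-code alphabet (distinct codes at least 2 apart) any
#' `r < 2` selects exactly the self-similar pairs, so the value is constant
#' over that whole range of `r`.
#'
#' @param x Numeric sequence with at least `m + 2` finite samples.
#' @param m Embedding dimension (template length), default 2.
#' @param r Absolute match tolerance, default 1.
#' @return A single nonnegative number (negative floating-point dust below
#'   1e-12 in magnitude is clamped to zero).
#' @seealso [sampen()], [fuzzyen()], [entropy_oracle()]
#' @examples
#' apen(rep(1, 60), m = 2, r = 1)  # 0: perfectly regular
#' @export
apen <- function(x, m = 2, r = 1) {
  .check_entropy_args(x, m, r)
  m <- as.integer(m)
  phi <- function(mm) {
    d <- .template_dists(x, mm)
    mean(log(rowMeans(d <= r)))
  }
  .clamp_zero(phi(m) - phi(m + 1L))
}

#' Sample Entropy
#'
#' Richman and Moorman's variant of approximate entropy: self-matches are
#' excluded and only the first `N - m` templates are compared, for both the
#' length-`m` and length-`m + 1` stages. The statistic is
#' `-ln(a^m(r) / b^m(r))`, the negative log ratio of the `m + 1` to `m`
#' template match probabilities. Since every `m + 1` match implies an `m`
#' match, the value is nonnegative whenever it is defined.
#'
#' With no off-diagonal matches at either stage the ratio involves a zero
#' and the statistic is undefined; `NA` is returned (never a substituted
#' large value) and downstream window statistics skip such windows.
#'
#' @inheritParams apen
#' @return A single nonnegative number, or `NA` when no template pair
#'   matches at one of the two stages.
#' @examples
#' sampen(rep(5, 30), m = 2, r = 0.5)   # 0
#' sampen(1:20, m = 2, r = 0.1)         # NA: no off-diagonal matches
#' @export
sampen <- function(x, m = 2, r = 1) {
  .check_entropy_args(x, m, r)
  m <- as.integer(m)
  nt <- length(x) - m          # templates compared at both stages
  dm <- .template_dists(x, m)[seq_len(nt), seq_len(nt), drop = FALSE]
  da <- .template_dists(x, m + 1L)                    # (N - m) templates
  b <- mean((rowSums(dm <= r) - 1) / (nt - 1))        # minus self-match
  a <- mean((rowSums(da <= r) - 1) / (nt - 1))
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

#' Fuzzy Entropy
#'
#' Chen et al.'s fuzzy relaxation of sample entropy: each template is first
#' centred by subtracting its own mean, and the hard match indicator is
#' replaced by the exponential similarity degree
#' `D_ij = exp(-(d_ij)^n / r)` of the centred Chebyshev distance `d_ij`.
#' Self-comparisons are excluded and the first `N - m` templates are used at
#' both stages; the statistic is `ln(phi^m(r)) - ln(phi^(m+1)(r))` where
#' `phi` is the grand mean similarity. Because every similarity degree is
#' strictly positive the measure is always defined.
#'
#' @inheritParams apen
#' @param n Gradient (power) of the exponential membership function;
#'   default 2, the common choice for this formulation.
#' @return A single nonnegative number (tiny negative floating-point
#'   residue is clamped to zero).
#' @examples
#' fuzzyen(rep(7, 60), m = 2, r = 1, n = 2)  # 0
#' @export
fuzzyen <- function(x, m = 2, r = 1, n = 2) {
  .check_entropy_args(x, m, r)
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("`n` must be a single positive number", call. = FALSE)
  m <- as.integer(m)
  nt <- length(x) - m
  phi <- function(mm) {
    d <- .template_dists_centered(x, mm)[seq_len(nt), seq_len(nt), drop = FALSE]
    sim <- exp(-(d^n) / r)
    mean((rowSums(sim) - 1) / (nt - 1))  # diagonal similarity is exactly 1
  }
  .clamp_zero(log(phi(m)) - log(phi(m + 1L)))
}

# Resolve a measure name to its window statistic. "mobility" is the indoor
# mobility baseline (room-transition count), not an entropy.
.measure_fun <- function(measure, m, r, n) {
  switch(measure,
    apen     = function(x) apen(x, m = m, r = r),
    sampen   = function(x) sampen(x, m = m, r = r),
    fuzzyen  = function(x) fuzzyen(x, m = m, r = r, n = n),
    mobility = function(x) indoor_mobility(x),
    stop("unknown measure: ", measure, call. = FALSE)
  )
}
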