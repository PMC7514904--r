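#' Brute-force entropy reference with computation trace
#'
#' Naive double-loop implementation of the three entropy measures, kept
#' deliberately independent of the vectorised versions ([apen()],
#' [sampen()], [fuzzyen()]) so it can serve as a testing reference. Along
#' with the value it returns the intermediate quantities of the
#' computation: per-template match frequencies, stage means, similarity
#' matrices and template baselines.
#'
#' Runs in O(N^2 m) with interpreted loops; intended for sequences up to a
#' few hundred samples.
#'
#' @param x Numeric sequence.
#' @param measure One of `"apen"`, `"sampen"`, `"fuzzyen"`.
#' @param m Embedding dimension.
#' @param r Absolute tolerance.
#' @param n Fuzzy exponent gradient (fuzzyen only).
#' @return A list with elements `value` (number, or `NA` for an undefined
#'   sample entropy) and `trace`, a list of intermediates:
#'   * apen: `C_m`, `C_m1` (match frequencies incl. self-match),
#'     `phi_m`, `phi_m1`;
#'   * sampen: `b_i`, `a_i`, `b`, `a`;
#'   * fuzzyen: `D_m`, `D_m1` (similarity matrices), `baseline_m`
#'     (template means), `phi_m`, `phi_m1`.
#' @examples
#' entropy_oracle(c(1, 3, 1, 3, 1, 3, 1, 3), "sampen", m = 2, r = 1)$value
#' @export
entropy_oracle <- function(x, measure = c("apen", "sampen", "fuzzyen"),
                           m = 2, r = 1, n = 2) {
  measure <- match.arg(measure)
  .check_entropy_args(x, m, r)
  m <- as.integer(m)
  N <- length(x)

  dist_ij <- function(i, j, mm) {
    d <- 0
    for (k in 0:(mm - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
    d
  }

  if (measure == "apen") {
    freq <- function(mm) {
      nt <- N - mm + 1L
      C <- numeric(nt)
      for (i in seq_len(nt)) {
        cnt <- 0L
        for (j in seq_len(nt)) if (dist_ij(i, j, mm) <= r) cnt <- cnt + 1L
        C[i] <- cnt / nt
      }
      C
    }
    C_m <- freq(m); C_m1 <- freq(m + 1L)
    phi_m <- mean(log(C_m)); phi_m1 <- mean(log(C_m1))
    return(list(value = phi_m - phi_m1,
                trace = list(C_m = C_m, C_m1 = C_m1,
                             phi_m = phi_m, phi_m1 = phi_m1)))
  }

  if (measure == "sampen") {
    nt <- N - m
    b_i <- numeric(nt); a_i <- numeric(nt)
    for (i in seq_len(nt)) {
      bc <- 0L; ac <- 0L
      for (j in seq_len(nt)) {
        if (j == i) next
        if (dist_ij(i, j, m) <= r) bc <- bc + 1L
        if (dist_ij(i, j, m + 1L) <= r) ac <- ac + 1L
      }
      b_i[i] <- bc / (nt - 1L); a_i[i] <- ac / (nt - 1L)
    }
    b <- mean(b_i); a <- mean(a_i)
    value <- if (a == 0 || b == 0) NA_real_ else -log(a / b)
    return(list(value = value,
                trace = list(b_i = b_i, a_i = a_i, b = b, a = a)))
  }

  # fuzzyen
  nt <- N - m
  sim_matrix <- function(mm) {
    D <- matrix(1, nt, nt)
    for (i in seq_len(nt)) {
      ti <- x[i:(i + mm - 1L)]; ti <- ti - mean(ti)
      for (j in seq_len(nt)) {
        if (j == i) next
        tj <- x[j:(j + mm - 1L)]; tj <- tj - mean(tj)
        D[i, j] <- exp(-(max(abs(ti - tj))^n) / r)
      }
    }
    D
  }
  D_m <- sim_matrix(m); D_m1 <- sim_matrix(m + 1L)
  phi_of <- function(D) mean((rowSums(D) - 1) / (nt - 1L))
  phi_m <- phi_of(D_m); phi_m1 <- phi_of(D_m1)
  baseline <- vapply(seq_len(nt), function(i) mean(x[i:(i + m - 1L)]), 0)
  list(value = log(phi_m) - log(phi_m1),
       trace = list(D_m = D_m, D_m1 = D_m1, baseline_m = baseline,
                    phi_m = phi_m, phi_m1 = phi_m1))
}
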