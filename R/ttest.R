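#' Pooled-variance two-sample Student t-test for one probe
#'
#' The probe-level test used throughout the pipeline: classical
#' pooled-variance Student's t with `df = n_a + n_b - 2` and a two-sided
#' p-value. Degenerate inputs follow documented conventions rather than
#' erroring, because a tiling array always contains a few saturated or
#' constant probes:
#' \itemize{
#'   \item both groups constant and equal: `t = 0`, `p = 1`;
#'   \item both groups constant and unequal: `t = +/-Inf`, `p = 0`;
#'   \item fewer than 2 non-missing values in either group: untestable,
#'     `t = NA`, `p = NA`.
#' }
#'
#' @param a,b numeric replicate values for the two genotypes; `NA`s dropped
#' @param var_equal if `FALSE`, use the Welch unequal-variance form instead
#'   of the classical pooled test
#' @return list with `t`, `p` (two-sided), `df`, and `testable`
#' @examples
#' probe_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~= 0.0213
#' @export
probe_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, testable = FALSE))
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  d <- ma - mb
  if (se == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df, testable = TRUE))
    return(list(t = sign(d) * Inf, p = 0, df = df, testable = TRUE))
  }
  t <- d / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, testable = TRUE)
}

# Vectorised pooled t over matrix rows (probes x replicates), NA-aware.
# Returns data.frame(t, p, df, testable) with one row per probe.
row_ttest <- function(A, B, var_equal = TRUE) {
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- replace_nan(rowMeans(A, na.rm = TRUE))
  mb <- replace_nan(rowMeans(B, na.rm = TRUE))
  ssa <- rowSums((A - ma)^2, na.rm = TRUE)
  ssb <- rowSums((B - mb)^2, na.rm = TRUE)
  testable <- na >= 2L & nb >= 2L
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- (ssa + ssb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    va <- ssa / pmax(na - 1, 1); vb <- ssb / pmax(nb - 1, 1)
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / pmax(na - 1, 1) + (vb / nb)^2 / pmax(nb - 1, 1))
  }
  d <- ma - mb
  se[!testable] <- NA_real_
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), pmax(df, 1)), 0)
  p[!is.na(se) & se == 0 & d == 0] <- 1
  t[!testable] <- NA_real_; p[!testable] <- NA_real_; df[!testable] <- NA_real_
  data.frame(t = t, p = p, df = df, testable = testable)
}
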