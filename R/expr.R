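#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged (arithmetic mean of Ct) per
#' sample/gene; then per sample `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - dCt_calibrator`, and the relative quantity
#' `RQ = 2^-ddCt`. The calibrator sample has RQ = 1 by construction. No
#' amplification-efficiency correction is applied (perfect doubling per
#' cycle is assumed).
#'
#' @param ct Long-format data frame with columns `sample`, `gene`, `ct`
#'   (cycle-threshold values, > 0) and optionally `replicate`.
#' @param target Gene to quantify.
#' @param reference Housekeeping/reference gene (e.g. GAPDH); must be
#'   measured in every sample.
#' @param calibrator Sample used as the unit of relative expression.
#' @return Data frame with one row per sample: `sample`, `ct_target`,
#'   `ct_reference`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @examples
#' ct <- data.frame(sample = rep(c("d0", "d2"), each = 2),
#'                  gene = rep(c("GAPDH", "MYOG"), 2),
#'                  ct = c(16, 24, 16, 23))
#' ddct(ct, target = "MYOG", reference = "GAPDH", calibrator = "d0")
#' @export
ddct <- function(ct, target, reference, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive", call. = FALSE)
  agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  samples <- unique(agg$sample)
  pick <- function(gene) {
    v <- agg$ct[agg$gene == gene][match(samples,
                                        agg$sample[agg$gene == gene])]
    stats::setNames(v, samples)
  }
  ct_t <- pick(target); ct_r <- pick(reference)
  if (anyNA(ct_r))
    stop("reference gene missing in sample(s): ",
         paste(samples[is.na(ct_r)], collapse = ", "), call. = FALSE)
  if (anyNA(ct_t))
    stop("target gene missing in sample(s): ",
         paste(samples[is.na(ct_t)], collapse = ", "), call. = FALSE)
  if (!calibrator %in% samples)
    stop("calibrator sample not found: ", calibrator, call. = FALSE)
  dct <- ct_t - ct_r
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, ct_target = unname(ct_t),
             ct_reference = unname(ct_r), delta_ct = unname(dct),
             delta_delta_ct = unname(ddct), rq = unname(2^(-ddct)))
}

#' Pearson correlation with an exact two-tailed p-value
#'
#' Product-moment correlation with significance from the exact t
#' transform: `t = r * sqrt(n-2) / sqrt(1 - r^2)` referred to the t
#' distribution on `n - 2` degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return List of class `correlation_result`: `r`, `n`, `t_stat`, `df`,
#'   `p`.
#' @examples
#' pearson_with_p(1:6, c(1.1, 2.3, 2.8, 4.5, 4.9, 6.2))
#' @export
pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))  # guard rounding past the boundary
  res <- pearson_p_from_r(r, n)
  structure(list(r = r, n = n, t_stat = res$t_stat, df = res$df,
                 p = res$p),
            class = "correlation_result")
}

#' p-value implied by a printed correlation coefficient
#'
#' Recovers the two-tailed p-value from a reported Pearson r and the
#' number of paired observations, via the t transform on `n - 2` degrees
#' of freedom. Useful for checking the internal consistency of published
#' (r, p) pairs when the raw series are not available.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return List with `t_stat`, `df`, `p`.
#' @examples
#' pearson_p_from_r(0.913, 7)$p  # 0.004 at 3 dp
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  df <- n - 2
  if (1 - r^2 <= 0) return(list(t_stat = Inf * sign(r), df = df, p = 0))
  t_stat <- r * sqrt(df) / sqrt(1 - r^2)
  list(t_stat = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df = df))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d): t = %.3f on %d df, p = %.4g\n",
              x$r, x$n, x$t_stat, x$df, x$p))
  invisible(x)
}
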