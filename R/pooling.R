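#' Expected PCR reaction count for pooled screening
#'
#' Under the mathematical-expectation (ME) pooling strategy, `N` samples are
#' tested in pools of `n`; every pool costs one reaction, and each positive
#' pool (one containing at least one carrier) triggers `n` individual
#' retests. With per-individual carrier probability `p`, a pool of size `n`
#' is positive with probability `1 - (1-p)^n`, so the expected total is
#'
#' \deqn{E[RT](n) = N/n + N (1 - (1-p)^n)}
#'
#' using a continuous pool count `N/n`. For `n = 1` there is no pooling and
#' the cost is exactly `N`.
#'
#' @param N Number of samples.
#' @param p Estimated per-individual carrier frequency, in `(0,1)`. Note
#'   this is a carrier (genotype-level) probability, not an allele
#'   frequency.
#' @param n Pool size(s); vectorised.
#' @return Expected reaction count, same length as `n`.
#' @examples
#' expected_reaction_times(640, 0.02, 8)  # 175.51, ceiling 176
#' @export
expected_reaction_times <- function(N, p, n) {
  stopifnot(N >= 1)
  stop_if_not_prob(p, "p")
  if (any(n < 1)) stop("pool size must be >= 1", call. = FALSE)
  if (any(n > N)) stop("pool size cannot exceed the sample count",
                       call. = FALSE)
  ifelse(n == 1, N, N / n + N * (1 - (1 - p)^n))
}

#' Optimal pool size under the ME objective
#'
#' Scans integer pool sizes `n = 2, ..., n_max`, minimising
#' [expected_reaction_times()]. Ties are broken toward the larger pool
#' size. The predicted reaction count is the ceiling of the expectation at
#' the optimum, and the predicted reduction rate compares it with testing
#' all `N` samples individually.
#'
#' @inheritParams expected_reaction_times
#' @param n_max Largest pool size considered (default `min(N, 64)`).
#' @return An object of class `me_design` with fields `N`, `p`, `n_opt`,
#'   `expected_rt`, `predicted_rt` (integer ceiling), `predicted_reduction`
#'   (fraction), and `curve`, a data frame of the scanned `(n, expected_rt)`
#'   pairs.
#' @examples
#' optimal_pool_size(640, 0.02)  # n_opt 8, pRT 176, pRR 72.50%
#' optimal_pool_size(640, 0.01)  # n_opt 11, pRT 126, pRR 80.31%
#' @export
optimal_pool_size <- function(N, p, n_max = min(N, 64L)) {
  stopifnot(n_max >= 2, n_max <= N)
  if (p >= 0.5)
    warning("carrier frequency >= 0.5: pooling saves nothing ",
            "(expected reaction count >= N for every pool size)",
            call. = FALSE)
  n <- seq.int(2L, n_max)
  e <- expected_reaction_times(N, p, n)
  # ties toward larger n: scan from the top
  best <- n[length(e) + 1L - which.min(rev(e))]
  e_best <- expected_reaction_times(N, p, best)
  prt <- as.integer(ceiling(e_best))
  structure(list(N = N, p = p, n_opt = best, expected_rt = e_best,
                 predicted_rt = prt,
                 predicted_reduction = (N - prt) / N,
                 curve = data.frame(n = n, expected_rt = e)),
            class = "me_design")
}

#' @export
print.me_design <- function(x, ...) {
  cat(sprintf(
    "ME pooling design: N = %d, carrier freq = %g\n  optimal pool size %d, expected RT %.2f -> predicted RT %d (reduction %.2f%%)\n",
    x$N, x$p, x$n_opt, x$expected_rt, x$predicted_rt,
    100 * x$predicted_reduction))
  invisible(x)
}

#' Partition sample ids into pools
#'
#' Chunks the ids sequentially into pools of size `n`; the final pool takes
#' the remainder and may be smaller. Optionally shuffles the ids first
#' under a seed.
#'
#' @param ids Character vector of sample ids.
#' @param n Pool size.
#' @param shuffle Permute ids before chunking?
#' @param seed Seed for the shuffle.
#' @return An object of class `pool_plan`: a list with `pools` (list of id
#'   vectors) and `n`.
#' @export
make_pools <- function(ids, n, shuffle = FALSE, seed = NULL) {
  if (length(ids) == 0) stop("empty id list", call. = FALSE)
  stopifnot(n >= 1, !anyDuplicated(ids))
  if (shuffle) ids <- with_seed(seed, sample(ids))
  pool_of <- ceiling(seq_along(ids) / n)
  structure(list(pools = unname(split(ids, pool_of)), n = as.integer(n)),
            class = "pool_plan")
}

#' Simulate one round of pooled screening plus retests
#'
#' A pool is truly positive when it contains at least one carrier (an
#' individual with one or two mutant alleles). The observed call flips the
#' truth with probability `fp_rate` (a negative pool reads positive; band
#' artefacts in the mixed template can do this) or `fn_rate` (a positive
#' pool reads negative). Every individual in an observed-positive pool is
#' retested individually and error-free; individuals in observed-negative
#' pools are called homozygous-reference without retest, so carriers in a
#' false-negative pool are miscalled — that leakage is part of the model.
#'
#' @param plan A [make_pools()] plan covering all ids in `pop`.
#' @param pop Population data frame with an `id` column and the genotype
#'   column `locus`.
#' @param locus Genotype column to screen.
#' @param mutant_allele Which allele (`"I"` or `"D"`) is the mutant whose
#'   carriers the screen detects.
#' @param fp_rate,fn_rate Pool-level false-positive / false-negative
#'   probabilities, in `[0,1]`.
#' @param seed Seed for the error draws.
#' @return An object of class `pool_outcome`: `pools` (data frame with
#'   pool index, size, true and observed positivity), `calls` (named
#'   genotype vector, one entry per individual), `realized_rt` (pool
#'   reactions + retests), and `reduction` relative to `nrow(pop)`
#'   individual tests.
#' @export
run_pools <- function(plan, pop, locus, mutant_allele = c("I", "D"),
                      fp_rate = 0, fn_rate = 0, seed = NULL) {
  mutant_allele <- match.arg(mutant_allele)
  stopifnot(inherits(plan, "pool_plan"), locus %in% names(pop))
  stop_if_not_prob(fp_rate, "fp_rate", open = FALSE)
  stop_if_not_prob(fn_rate, "fn_rate", open = FALSE)
  ids <- unlist(plan$pools, use.names = FALSE)
  if (!setequal(ids, pop$id))
    stop("pool plan does not cover exactly the population ids",
         call. = FALSE)
  geno <- stats::setNames(pop[[locus]], pop$id)
  carrier <- dosage_from_genotype(geno, mutant_allele) > 0
  ref_homo <- genotype_from_dosage(0L, mutant_allele)

  truth <- vapply(plan$pools, function(p) any(carrier[p]), logical(1))
  observed <- with_seed(seed, {
    flip_up <- stats::runif(length(truth)) < fp_rate
    flip_dn <- stats::runif(length(truth)) < fn_rate
    ifelse(truth, !flip_dn, flip_up)
  })
  sizes <- lengths(plan$pools)
  calls <- stats::setNames(rep(ref_homo, length(ids)), ids)
  retested <- unlist(plan$pools[observed], use.names = FALSE)
  calls[retested] <- geno[retested]

  structure(list(
    pools = data.frame(pool = seq_along(sizes), size = sizes,
                       true_positive = truth, observed_positive = observed),
    calls = calls,
    realized_rt = length(sizes) + sum(sizes[observed]),
    reduction = (nrow(pop) - (length(sizes) + sum(sizes[observed]))) /
      nrow(pop)),
    class = "pool_outcome")
}

#' Reaction-count reduction rate
#'
#' Fractional saving of a realised reaction count relative to testing all
#' `N` samples individually: `(N - realized_rt) / N`. Negative when pooling
#' cost more than individual testing.
#'
#' @param realized_rt Realised total reaction count.
#' @param N Number of samples.
#' @return Fraction (may be negative).
#' @examples
#' reduction_rate(221, 640)  # 0.6547
#' @export
reduction_rate <- function(realized_rt, N) {
  if (N == 0) stop("N must be positive", call. = FALSE)
  stopifnot(realized_rt >= 0)
  (N - realized_rt) / N
}
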