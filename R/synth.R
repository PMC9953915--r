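#' Two-locus haplotype frequencies from marginals and D'
#'
#' Builds the four-haplotype frequency vector for two biallelic loci from
#' the marginal mutant-allele frequencies and a target normalised
#' disequilibrium D'. The raw coefficient is `D = D' * Dmax`, where for a
#' coupling-phase (positive) D, `Dmax = min(pA*(1-pB), (1-pA)*pB)`, and for
#' repulsion `Dmax = min(pA*pB, (1-pA)*(1-pB))` with D taken negative.
#' Haplotypes are labelled by the mutant/reference state at each locus.
#'
#' @param p_a,p_b Mutant-allele frequencies at the two loci.
#' @param d_prime Target D' in `[0,1]`.
#' @param coupling `"coupling"` (mutant alleles co-occur) or `"repulsion"`.
#' @return Named numeric vector of length 4 (`MM`, `MR`, `RM`, `RR`; M =
#'   mutant, R = reference, first letter locus A) summing to 1, with the
#'   realised `D` as attribute `"D"`.
#' @export
haplotype_freqs <- function(p_a, p_b, d_prime, coupling = "coupling") {
  stop_if_not_prob(p_a, "p_a", open = FALSE)
  stop_if_not_prob(p_b, "p_b", open = FALSE)
  stop_if_not_prob(d_prime, "d_prime", open = FALSE)
  d_max <- if (coupling == "coupling")
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d <- d_prime * d_max * (if (coupling == "coupling") 1 else -1)
  h <- c(MM = p_a * p_b + d,
         MR = p_a * (1 - p_b) - d,
         RM = (1 - p_a) * p_b - d,
         RR = (1 - p_a) * (1 - p_b) + d)
  if (any(h < -1e-12))
    stop(sprintf(
      "infeasible D'/frequency combination: haplotype %s would have frequency %.3g",
      names(h)[which.min(h)], min(h)), call. = FALSE)
  h <- pmax(h, 0)
  attr(h, "D") <- d
  h
}

#' Simulate genotypes for a herd
#'
#' Each individual receives two haplotypes drawn independently from the
#' two-locus haplotype frequency vector implied by the configured marginal
#' allele frequencies and target D' (see [haplotype_freqs()]); per-locus
#' genotypes are the unordered allele pairs. Under D' = 0 the loci are
#' independent; under D' = 1 one haplotype class is absent. Sexes are
#' assigned by permuting the configured counts.
#'
#' @param config A [herd_config()].
#' @return A data frame (one row per individual) with columns `id`, `sex`
#'   and one genotype column (`II`/`ID`/`DD`) per locus; the simulated
#'   haplotype pairs are kept in attribute `"haplotypes"` (an
#'   `n x 2` integer matrix indexing `MM`/`MR`/`RM`/`RR`) so that
#'   phase-aware quantities such as the realised D' remain recoverable.
#' @examples
#' herd <- simulate_genotypes(sdbcgr_herd_config(seed = 42))
#' table(herd$P1)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "herd_config"))
  n <- config$n_individuals
  with_seed(config$seed, {
    sex <- sample(rep(names(config$sex_counts), config$sex_counts))
    pop <- data.frame(id = sprintf("ind%04d", seq_len(n)), sex = sex,
                      stringsAsFactors = FALSE)
    freqs <- vapply(config$loci, `[[`, numeric(1), "mutant_freq")
    if (length(config$loci) == 2) {
      h <- haplotype_freqs(freqs[1], freqs[2], config$d_prime,
                           config$coupling)
      hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = h),
                    ncol = 2)
      # haplotype index -> mutant dosage at locus A (cols 1,2) / B (1,3)
      mut_a <- c(1L, 1L, 0L, 0L); mut_b <- c(1L, 0L, 1L, 0L)
      dos <- cbind(mut_a[hap[, 1]] + mut_a[hap[, 2]],
                   mut_b[hap[, 1]] + mut_b[hap[, 2]])
    } else {
      hap <- matrix(stats::rbinom(2L * n, 1L, freqs[1]), ncol = 2)
      hap <- 2L - hap  # 1 = mutant, 2 = reference, matching M*/R* order
      dos <- cbind(rowSums(hap == 1L))
    }
    for (j in seq_along(config$loci))
      pop[[config$loci[[j]]$name]] <-
        genotype_from_dosage(dos[, j], config$loci[[j]]$mutant_allele)
    attr(pop, "haplotypes") <- hap
    pop
  })
}

#' Simulate trait values on a genotyped herd
#'
#' For each trait specification, every eligible individual (matching sex
#' restriction, genotype among those the spec parameterises) receives a
#' value drawn from `Normal(mean_g, SE_g * sqrt(n_g))`, the population
#' distribution implied by a reported group mean, standard error and group
#' size. Negative draws are resampled, since carcass weights cannot be
#' negative. Individuals that fail the sex restriction, carry an
#' unparameterised genotype, or are sampled missing get `NA`.
#'
#' @param pop Population data frame from [simulate_genotypes()].
#' @param specs List of [trait_spec()] objects.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @return `pop` with one numeric column appended per trait.
#' @export
simulate_traits <- function(pop, specs, seed = NULL) {
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "trait_spec")))
  for (s in specs) {
    if (!s$locus %in% names(pop))
      stop(sprintf("trait '%s' references unknown locus '%s'",
                   s$trait, s$locus), call. = FALSE)
    bad <- setdiff(names(s$means), GENOTYPES)
    if (length(bad))
      stop("unknown genotype label in trait spec: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    for (s in specs) {
      g <- pop[[s$locus]]
      eligible <- g %in% names(s$means)
      if (!is.null(s$sex)) eligible <- eligible & pop$sex == s$sex
      if (s$missing_rate > 0)
        eligible <- eligible &
          stats::rbinom(nrow(pop), 1L, 1 - s$missing_rate) == 1L
      val <- rep(NA_real_, nrow(pop))
      idx <- which(eligible)
      if (length(idx)) {
        mu <- s$means[g[idx]]
        sd <- (s$ses * sqrt(s$ns))[g[idx]]
        v <- stats::rnorm(length(idx), mu, sd)
        while (any(neg <- v < 0))
          v[neg] <- stats::rnorm(sum(neg), mu[neg], sd[neg])
        val[idx] <- v
      }
      pop[[s$trait]] <- val
    }
    pop
  })
}

#' Simulate a complete herd (genotypes + traits)
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_traits()] under the configuration's seed (traits use
#' `seed + 1` so the two stages draw from distinct streams).
#'
#' @inheritParams simulate_genotypes
#' @return Population data frame with genotype and trait columns.
#' @export
simulate_herd <- function(config) {
  pop <- simulate_genotypes(config)
  simulate_traits(pop, config$trait_specs, seed = config$seed + 1L)
}
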