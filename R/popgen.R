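#' Tally II/ID/DD genotype counts
#'
#' @param genotypes Character vector of genotype calls (`NA` allowed and
#'   dropped).
#' @return Named integer vector with entries `II`, `ID`, `DD`.
#' @export
genotype_counts <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  bad <- setdiff(unique(g), GENOTYPES)
  if (length(bad))
    stop("unknown genotype token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  table(factor(g, levels = GENOTYPES)) |> as.integer() |>
    stats::setNames(GENOTYPES)
}

#' Single-locus population-genetic statistics
#'
#' From II/ID/DD genotype counts, computes allele frequencies by gene
#' counting (`p_I = (2 n_II + n_ID) / 2n`), gene homozygosity
#' `Ho = p^2 + q^2`, expected heterozygosity `He = 1 - Ho`, effective
#' allele number `Ne = 1/Ho`, the two-allele polymorphism information
#' content `PIC = 1 - p^2 - q^2 - 2 p^2 q^2` (Botstein's formula
#' specialised to two alleles), and a Hardy-Weinberg equilibrium test
#' against the expected proportions `p^2, 2pq, q^2`.
#'
#' @param counts Named vector of genotype counts (`II`, `ID`, `DD`), or a
#'   character vector of genotype calls which is tallied first.
#' @param hwe_method `"chisq"` for the Pearson chi-square on 1 df (no
#'   continuity correction), or `"exact"` for the exact conditional test
#'   enumerating heterozygote counts given the allele counts.
#' @return An object of class `locus_stats` with fields `n`,
#'   `genotype_freqs`, `allele_freqs` (named `I`, `D`), `Ho`, `He`, `Ne`,
#'   `PIC`, `hwe_chi2`, `hwe_p`. At a monomorphic locus the HWE statistic
#'   and p are `NA` (the test is undefined).
#' @examples
#' locus_stats(c(II = 0, ID = 43, DD = 373))   # He 0.098, Ne 1.109, PIC 0.093
#' locus_stats(c(II = 628, ID = 12, DD = 0))   # Ne 1.019
#' @export
locus_stats <- function(counts, hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  if (is.character(counts)) counts <- genotype_counts(counts)
  if (is.null(names(counts)) || !all(GENOTYPES %in% names(counts)))
    stop("`counts` must be named with II, ID, DD", call. = FALSE)
  counts <- counts[GENOTYPES]
  if (any(counts < 0)) stop("negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("no genotyped individuals", call. = FALSE)
  p <- (2 * counts[["II"]] + counts[["ID"]]) / (2 * n)  # freq of I
  q <- 1 - p
  ho <- p^2 + q^2
  monomorphic <- p == 0 || p == 1
  if (monomorphic) {
    chi2 <- p_hwe <- NA_real_
  } else if (hwe_method == "chisq") {
    expected <- n * c(p^2, 2 * p * q, q^2)
    chi2 <- sum((counts - expected)^2 / expected)
    p_hwe <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p_hwe <- hwe_exact_p(counts[["II"]], counts[["ID"]], counts[["DD"]])
  }
  structure(list(n = n,
                 genotype_freqs = counts / n,
                 allele_freqs = c(I = p, D = q),
                 Ho = ho, He = 1 - ho, Ne = 1 / ho,
                 PIC = 1 - p^2 - q^2 - 2 * p^2 * q^2,
                 hwe_chi2 = chi2, hwe_p = p_hwe),
            class = "locus_stats")
}

# Exact HWE test: enumerate the conditional distribution of the
# heterozygote count given the rare-allele count, sum probabilities
# <= that of the observed table (Wigginton-style two-sided p).
hwe_exact_p <- function(n_ii, n_id, n_dd) {
  n <- n_ii + n_id + n_dd
  n_rare <- min(2 * n_ii + n_id, 2 * n_dd + n_id)
  het <- seq.int(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(het, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[match(n_id, het)] * (1 + 1e-9)]))
}

#' @export
print.locus_stats <- function(x, ...) {
  cat(sprintf(
    "Locus statistics (n = %d)\n  genotype freqs: II %.3f  ID %.3f  DD %.3f\n  allele freqs:   I %.3f  D %.3f\n  Ho %.3f  He %.3f  Ne %.3f  PIC %.3f\n  HWE: chi2 = %s, p = %s\n",
    x$n, x$genotype_freqs[["II"]], x$genotype_freqs[["ID"]],
    x$genotype_freqs[["DD"]], x$allele_freqs[["I"]], x$allele_freqs[["D"]],
    x$Ho, x$He, x$Ne, x$PIC,
    format(x$hwe_chi2, digits = 3), format(x$hwe_p, digits = 3)))
  invisible(x)
}

#' Cross-tabulate two-locus genotypes
#'
#' @param pop Population data frame.
#' @param locus_a,locus_b Genotype column names.
#' @return 3x3 matrix of counts, rows = `locus_a` genotypes (II/ID/DD),
#'   columns = `locus_b` genotypes; individuals missing either call are
#'   dropped.
#' @export
two_locus_counts <- function(pop, locus_a, locus_b) {
  stopifnot(locus_a %in% names(pop), locus_b %in% names(pop))
  ok <- !is.na(pop[[locus_a]]) & !is.na(pop[[locus_b]])
  table(factor(pop[[locus_a]][ok], levels = GENOTYPES),
        factor(pop[[locus_b]][ok], levels = GENOTYPES)) |>
    unclass()
}

#' EM haplotype frequencies and linkage disequilibrium for two loci
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotype counts by expectation-maximisation. Only the double
#' heterozygote (ID/ID) is phase-ambiguous: its gametes are either
#' `I-I + D-D` or `I-D + D-I`, split each E-step in proportion to the
#' current products of haplotype frequencies. The EM is initialised at
#' linkage equilibrium (products of the observed allele frequencies) and
#' iterated until the log-likelihood changes by less than `tol` or
#' `max_iter` iterations.
#'
#' Disequilibrium is reported for the `I-I` haplotype:
#' `D = f(I-I) - p_A p_B` with `p_A`, `p_B` the frequencies of allele I at
#' each locus; `D' = |D| / Dmax` where `Dmax = min(p_A q_B, q_A p_B)` for
#' `D > 0` and `min(p_A p_B, q_A q_B)` for `D < 0`; and
#' `r^2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' @param counts 3x3 matrix of two-locus genotype counts as produced by
#'   [two_locus_counts()] (rows/columns ordered II, ID, DD).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @return An object of class `two_locus_ld`: `haplotype_freqs` (named
#'   `I-I`, `I-D`, `D-I`, `D-D`), `allele_freqs` per locus, `D`, `D_prime`,
#'   `r2`, `ld_defined` (FALSE when a locus is monomorphic, in which case
#'   `D`, `D_prime` and `r2` are `NA` with a warning), `em_iterations`,
#'   `em_loglik`, and the per-iteration `loglik_trace`.
#' @export
em_haplotypes <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("empty genotype table", call. = FALSE)
  # allele-I frequency at each locus from genotype marginals
  dos <- c(2, 1, 0)
  p_a <- sum(rowSums(counts) * dos) / (2 * n)
  p_b <- sum(colSums(counts) * dos) / (2 * n)

  # haplotype order: 1 I-I, 2 I-D, 3 D-I, 4 D-D
  h <- c(p_a * p_b, p_a * (1 - p_b), (1 - p_a) * p_b,
         (1 - p_a) * (1 - p_b))
  h <- pmax(h, 1e-12); h <- h / sum(h)

  # fixed gamete contributions of the 8 unambiguous cells:
  # cell (i,j) with dosages (a,b) contributes haplotypes deterministically
  base <- matrix(0, 1, 4)
  fixed <- matrix(0, nrow = 9, ncol = 4)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    a <- dos[i]; b <- dos[j]
    if (a == 1 && b == 1) next  # double het handled in E-step
    # locus A gametes: a==2 -> I,I; a==1 -> I,D; a==0 -> D,D (same for B)
    ga <- c(rep("I", a), rep("D", 2 - a))
    gb <- c(rep("I", b), rep("D", 2 - b))
    # unambiguous pairing: when either locus is homozygous, both pairings
    # give identical multisets of haplotypes
    idx <- function(x, y) (x == "D") * 2 + (y == "D") + 1
    fixed[k, ] <- tabulate(c(idx(ga[1], gb[1]), idx(ga[2], gb[2])),
                           nbins = 4)
  }
  cnt <- as.vector(t(counts))  # row-major: cell k = (i,j)
  dh <- counts[2, 2]           # double heterozygotes
  fixed_tot <- colSums(fixed * cnt)

  loglik <- function(h) {
    # cell probabilities under random union of gametes
    pr <- numeric(9); k <- 0
    for (i in 1:3) for (j in 1:3) {
      k <- k + 1
      if (dos[i] == 1 && dos[j] == 1) {
        pr[k] <- 2 * h[1] * h[4] + 2 * h[2] * h[3]
      } else {
        hap <- which(fixed[k, ] > 0)
        pr[k] <- if (length(hap) == 1) h[hap]^2
        else 2 * h[hap[1]] * h[hap[2]]
      }
    }
    sum(cnt[pr > 0] * log(pr[pr > 0]))
  }

  trace <- ll <- loglik(h)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: split double heterozygotes between the two phasings
    cis <- h[1] * h[4]; trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    expected <- fixed_tot +
      dh * c(w, 1 - w, 1 - w, w)
    h_new <- expected / (2 * n)
    ll_new <- loglik(h_new)
    trace <- c(trace, ll_new)
    done <- abs(ll_new - ll) < tol || iter >= max_iter
    h <- h_new; ll <- ll_new
    if (done) break
  }
  names(h) <- c("I-I", "I-D", "D-I", "D-D")

  mono <- p_a %in% c(0, 1) || p_b %in% c(0, 1)
  if (mono) {
    warning("monomorphic locus: D', r2 undefined", call. = FALSE)
    D <- dprime <- r2 <- NA_real_
  } else {
    D <- h[["I-I"]] - p_a * p_b
    d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
    else min(p_a * p_b, (1 - p_a) * (1 - p_b))
    dprime <- if (d_max == 0) 0 else abs(D) / d_max
    r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  }
  structure(list(haplotype_freqs = h,
                 allele_freqs = list(locus_a = c(I = p_a, D = 1 - p_a),
                                     locus_b = c(I = p_b, D = 1 - p_b)),
                 D = unname(D), D_prime = unname(dprime), r2 = unname(r2),
                 ld_defined = !mono,
                 em_iterations = iter, em_loglik = ll,
                 loglik_trace = trace),
            class = "two_locus_ld")
}

#' @export
print.two_locus_ld <- function(x, ...) {
  cat("Two-locus haplotype/LD estimate (EM)\n  haplotype freqs:",
      paste(sprintf("%s %.4f", names(x$haplotype_freqs),
                    x$haplotype_freqs), collapse = "  "),
      sprintf("\n  D = %.4g, D' = %.3f, r2 = %.3f (%d iterations)\n",
              x$D, x$D_prime, x$r2, x$em_iterations))
  invisible(x)
}

#' Table of locus statistics for a population
#'
#' @param pop Population data frame.
#' @param loci Genotype column names.
#' @inheritParams locus_stats
#' @return Data frame, one row per locus, with genotype and allele
#'   frequencies, Ho, He, Ne, PIC and the HWE p-value.
#' @export
locus_stats_table <- function(pop, loci, hwe_method = "chisq") {
  rows <- lapply(loci, function(l) {
    s <- locus_stats(genotype_counts(pop[[l]]), hwe_method = hwe_method)
    data.frame(locus = l, n = s$n,
               freq_II = s$genotype_freqs[["II"]],
               freq_ID = s$genotype_freqs[["ID"]],
               freq_DD = s$genotype_freqs[["DD"]],
               freq_I = s$allele_freqs[["I"]],
               freq_D = s$allele_freqs[["D"]],
               Ho = s$Ho, He = s$He, Ne = s$Ne, PIC = s$PIC,
               hwe_p = s$hwe_p)
  })
  do.call(rbind, rows)
}
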