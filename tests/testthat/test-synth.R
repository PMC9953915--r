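test_that("degenerate mutant frequency 0 gives all homozygous-reference", {
  cfg <- two_locus_config(200, p1 = 0, p2 = 0, d_prime = 0, seed = 3)
  herd <- simulate_genotypes(cfg)
  expect_true(all(herd$L1 == "DD"))  # mutant at L1 is I
  expect_true(all(herd$L2 == "II"))  # mutant at L2 is D
})

test_that("sample allele frequencies stay within 3 binomial SD of targets", {
  cfg <- two_locus_config(640, p1 = 0.052, p2 = 0.009, d_prime = 1,
                          seed = 11)
  herd <- simulate_genotypes(cfg)
  for (spec in list(list(col = "L1", p = 0.052, mutant = "I"),
                    list(col = "L2", p = 0.009, mutant = "D"))) {
    cnt <- genotype_counts(herd[[spec$col]])
    s <- locus_stats(cnt)
    p_hat <- if (spec$mutant == "I") s$allele_freqs[["I"]]
    else s$allele_freqs[["D"]]
    se <- sqrt(spec$p * (1 - spec$p) / (2 * 640))
    expect_lt(abs(p_hat - spec$p), 3 * se + 1e-12)
  }
})

test_that("D' = 0 yields statistically independent loci across seeds", {
  # chi-square independence p-values should look uniform over replicates
  pvals <- vapply(1:100, function(s) {
    herd <- simulate_genotypes(two_locus_config(10000, p1 = 0.05,
                                                p2 = 0.05, d_prime = 0,
                                                seed = s))
    tab <- two_locus_counts(herd, "L1", "L2")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    suppressWarnings(chisq.test(tab))$p.value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(mean(pvals < 0.05), 0)   # not degenerate at 1 either
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("large-herd genotype frequencies match Hardy-Weinberg expectations", {
  p <- 0.052
  cfg <- herd_config(1e5, sex_counts = c(female = 1e5),
                     loci = locus_spec("L1", "I", p), seed = 5)
  herd <- simulate_genotypes(cfg)
  cnt <- genotype_counts(herd$L1)
  expected <- 1e5 * c(II = p^2, ID = 2 * p * (1 - p), DD = (1 - p)^2)
  for (g in names(expected)) {
    sd_g <- sqrt(expected[[g]] * (1 - expected[[g]] / 1e5))
    expect_lt(abs(cnt[[g]] - expected[[g]]), 3 * sd_g + 1e-9)
  }
})

test_that("realised haplotype D' tracks the target before genotype collapse", {
  for (target in c(0.3, 0.7, 1)) {
    herd <- simulate_genotypes(two_locus_config(20000, p1 = 0.2, p2 = 0.1,
                                                d_prime = target,
                                                seed = 17 + round(10 * target)))
    hap <- attr(herd, "haplotypes")
    h <- tabulate(c(hap), nbins = 4) / (2 * nrow(herd))
    p_a <- h[1] + h[2]; p_b <- h[1] + h[3]
    d <- h[1] - p_a * p_b
    d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
    else min(p_a * p_b, (1 - p_a) * (1 - p_b))
    expect_lt(abs(d / d_max - target), 0.05)
  }
})

test_that("D' is bounded and the boundary empties one haplotype class", {
  # D = D' * Dmax keeps every haplotype frequency admissible across the
  # whole D' range; D' = 1 pins the limiting class to exactly zero, and
  # anything beyond the [0,1] range is rejected up front
  h <- haplotype_freqs(0.01, 0.01, 1, coupling = "repulsion")
  expect_equal(min(h), 0)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  h2 <- haplotype_freqs(0.052, 0.009, 1, coupling = "coupling")
  expect_equal(min(h2), 0, tolerance = 1e-15)
  expect_error(haplotype_freqs(0.1, 0.1, 1.2), "d_prime")
  expect_error(two_locus_config(100, d_prime = 1.5), "d_prime")
})

test_that("fixed seed reproduces the herd byte for byte", {
  cfg <- sdbcgr_herd_config(seed = 99)
  h1 <- simulate_herd(cfg)
  h2 <- simulate_herd(cfg)
  expect_identical(h1, h2)
  h3 <- simulate_herd(sdbcgr_herd_config(seed = 100))
  expect_false(identical(h1$P1, h3$P1))
})

test_that("zero-noise traits collapse to the genotype means", {
  herd <- trait_herd(300, means = c(II = 2, ID = 1.5, DD = 1),
                     ses = c(II = 1e-12, ID = 1e-12, DD = 1e-12),
                     ns = c(II = 10, ID = 10, DD = 10), seed = 4)
  means <- c(II = 2, ID = 1.5, DD = 1)
  expect_true(all(abs(herd$y - means[herd$L1]) < 1e-9, na.rm = TRUE))
})

test_that("missing_rate = 1 empties the trait and the scan skips it", {
  herd <- trait_herd(100, means = c(II = 2, DD = 1),
                     ses = c(II = 0.1, DD = 0.1),
                     ns = c(II = 10, DD = 10), seed = 8, missing_rate = 1)
  expect_true(all(is.na(herd$y)))
  res <- association_scan(herd, "L1", "y")
  expect_true(all(is.na(res$p)))
  expect_match(res$note[1], "fewer than 2 testable groups")
})

test_that("trait values are never negative", {
  herd <- trait_herd(2000, means = c(II = 0.05, DD = 0.02),
                     ses = c(II = 0.5, DD = 0.5),
                     ns = c(II = 4, DD = 4), seed = 21)
  expect_true(all(herd$y >= 0, na.rm = TRUE))
})

test_that("sex restriction and unknown-genotype specs behave as declared", {
  cfg <- herd_config(100, sex_counts = c(male = 40, female = 58,
                                         missing = 2),
                     loci = locus_spec("L1", "I", 0.3),
                     seed = 2)
  herd <- simulate_genotypes(cfg)
  spec <- trait_spec("y", "L1", means = c(II = 2, ID = 1.5, DD = 1),
                     ses = c(II = .1, ID = .1, DD = .1),
                     ns = c(II = 5, ID = 5, DD = 5), sex = "female")
  out <- simulate_traits(herd, spec, seed = 3)
  expect_true(all(is.na(out$y[out$sex != "female"])))
  expect_true(all(!is.na(out$y[out$sex == "female"])))
  expect_error(simulate_traits(herd, list(structure(
    modifyList(unclass(spec), list(means = c(XX = 1))),
    class = "trait_spec"))), "unknown genotype")
})

test_that("simulated group contrasts are recovered by the downstream t-test", {
  # two-genotype trait with a clear separation: the t-test should find the
  # right direction in nearly every replicate
  hits <- vapply(1:200, function(s) {
    herd <- trait_herd(500, means = c(ID = 1.30, II = 1.02),
                       ses = c(ID = 0.10, II = 0.02),
                       ns = c(ID = 29, II = 163),
                       geno_freq_I = 0.948, seed = 1000 + s)
    a <- herd$y[herd$L1 == "ID"]; b <- herd$y[herd$L1 == "II"]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) return(NA)
    mean(a, na.rm = TRUE) > mean(b, na.rm = TRUE)
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.95)
})

test_that("herd configs validate their invariants", {
  expect_error(herd_config(10, sex_counts = c(male = 4, female = 4),
                           loci = locus_spec("L", "I", 0.1)),
               "sum to 8")
  expect_error(locus_spec("L", "I", 1.2), "mutant_freq")
  expect_error(trait_spec("y", "L", means = c(II = 1), ses = c(II = 0),
                          ns = c(II = 5)), "ses > 0")
})
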