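test_that("pooled two-group t-test matches hand computation", {
  tt <- t_test_two_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.6742, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.02131, tolerance = 1e-4)
  expect_equal(tt$groups$mean, c(2, 5))
  expect_equal(tt$groups$se, rep(1 / sqrt(3), 2), tolerance = 1e-9)
  # significant at 0.05 but not 0.01: distinct lowercase, shared uppercase
  expect_setequal(tt$groups$letters_05, c("a", "b"))
  expect_identical(tt$groups$letters_01, c("A", "A"))
})

test_that("identical groups give t = 0, p = 1; degenerate variance handled", {
  tt <- t_test_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  flat <- t_test_two_groups(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p, 1)
  expect_equal(flat$statistic, 0)
  expect_error(t_test_two_groups(1, c(1, 2)), "at least 2")
})

test_that("Welch variant is available and differs under variance imbalance", {
  a <- c(1, 2, 3, 4, 50); b <- c(2.1, 2.2, 2.3, 2.0)
  tp <- t_test_two_groups(a, b, variant = "pooled")
  tw <- t_test_two_groups(a, b, variant = "welch")
  expect_false(isTRUE(all.equal(tp$p, tw$p)))
  expect_equal(tw$p, t.test(a, b)$p.value)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  withr::with_seed(15, {
    a <- rnorm(20, 1); b <- rnorm(25, 1.4)
  })
  av <- anova_one_way(list(g1 = a, g2 = b))
  tt <- t_test_two_groups(a, b)
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(av$p, tt$p, tolerance = 1e-9)
})

test_that("ANOVA type-I error is calibrated under the null", {
  rejections <- withr::with_seed(123, vapply(seq_len(1000), function(i) {
    g <- lapply(1:3, function(k) rnorm(50, 5, 1))
    names(g) <- c("A", "B", "C")
    anova_one_way(g)$p < 0.05
  }, logical(1)))
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("undersized groups are reported but excluded from the omnibus test", {
  g <- list(big1 = rnorm(30, 1), big2 = rnorm(30, 1.2),
            big3 = rnorm(30, 1.1), tiny = 0.7)
  av <- anova_one_way(g)
  expect_identical(nrow(av$groups), 4L)
  expect_false(av$groups$tested[av$groups$group == "tiny"])
  expect_equal(av$df[1], 2)   # 3 testable groups
  expect_error(anova_one_way(list(a = 1, b = 2)), "fewer than 2")
})

test_that("diplotype contrast simulated from published moments is detected", {
  # two female diplotype groups with well-separated means; letters a/b
  # should mark the ordering whenever the test is significant
  hits <- withr::with_seed(456, vapply(seq_len(200), function(i) {
    g <- list("DD-II" = rnorm(163, 1.02, 0.02 * sqrt(163)),
              "ID-II" = rnorm(27, 1.30, 0.11 * sqrt(27)))
    av <- anova_one_way(g)
    dir_ok <- av$groups$mean[av$groups$group == "ID-II"] >
      av$groups$mean[av$groups$group == "DD-II"]
    if (av$p < 0.05) {
      lets <- setNames(av$groups$letters_05, av$groups$group)
      dir_ok && lets[["ID-II"]] == "a" && lets[["DD-II"]] == "b"
    } else dir_ok
  }, logical(1)))
  expect_gt(mean(hits), 0.9)
})

test_that("letter assignment is invariant to group ordering", {
  means <- c(x = 5, y = 3, z = 1)
  pm <- matrix(c(NA, 0.2, 0.001,
                 0.2, NA, 0.3,
                 0.001, 0.3, NA), 3, 3,
               dimnames = list(names(means), names(means)))
  l1 <- assign_letters(means, pm)
  perm <- c("z", "x", "y")
  l2 <- assign_letters(means[perm], pm[perm, perm])
  expect_identical(l1[names(l2)], l2)
  # x and z differ; y shares with both
  expect_false(any(strsplit(l1[["x"]], "")[[1]] %in%
                     strsplit(l1[["z"]], "")[[1]]))
  expect_true(any(strsplit(l1[["y"]], "")[[1]] %in%
                    strsplit(l1[["x"]], "")[[1]]))
})

test_that("single-sex model drops sex and reproduces the one-way results", {
  herd <- trait_herd(300, means = c(II = 2, ID = 1.7, DD = 1.5),
                     ses = c(II = .2, ID = .2, DD = .2),
                     ns = c(II = 10, ID = 10, DD = 10), seed = 61)
  fit <- glm_fit(herd, "y", "L1")
  expect_identical(fit$dropped, "sex")
  g <- split(herd$y[!is.na(herd$y)], herd$L1[!is.na(herd$y)])
  av <- anova_one_way(g)
  expect_equal(fit$effects$F[fit$effects$term == "genotype"], av$statistic,
               tolerance = 1e-9)
  expect_equal(fit$effects$p[fit$effects$term == "genotype"], av$p,
               tolerance = 1e-9)
})

test_that("single-sex two-group model reproduces the pooled t-test p", {
  herd <- trait_herd(250, means = c(II = 2, DD = 1.8),
                     ses = c(II = .2, DD = .2),
                     ns = c(II = 10, DD = 10), geno_freq_I = 0.5, seed = 62)
  fit <- glm_fit(herd, "y", "L1")
  tt <- t_test_two_groups(herd$y[herd$L1 == "II"],
                          herd$y[herd$L1 == "DD"])
  expect_equal(fit$effects$p[fit$effects$term == "genotype"], tt$p,
               tolerance = 1e-9)
})

test_that("the genotype + sex model recovers a known effect size", {
  # additive effect of 0.3 kg per genotype contrast, both sexes present
  est <- vapply(1:200, function(s) {
    cfg <- herd_config(400, sex_counts = c(male = 150, female = 250),
                       loci = locus_spec("L1", "I", 0.4), seed = 7000 + s)
    herd <- simulate_genotypes(cfg)
    delta <- c(II = 0.3, ID = 0.0, DD = 0.0)
    sex_eff <- ifelse(herd$sex == "male", 0.5, 0)
    herd$y <- withr::with_seed(7000 + s,
                               5 + delta[herd$L1] + sex_eff + rnorm(400, 0, 0.4))
    fit <- glm_fit(herd, "y", "L1")
    unname(fit$coefficients["genotypeII"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.03)
})

test_that("genotype-effect p-values are uniform under the null model", {
  pvals <- vapply(1:1000, function(s) {
    cfg <- herd_config(200, sex_counts = c(male = 80, female = 120),
                       loci = locus_spec("L1", "I", 0.4), seed = 9000 + s)
    herd <- simulate_genotypes(cfg)
    herd$y <- withr::with_seed(9000 + s, rnorm(200, 5, 1))
    fit <- glm_fit(herd, "y", "L1")
    fit$effects$p[fit$effects$term == "genotype"]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("association scan handles empty input, errors and ranking", {
  herd <- trait_herd(200, means = c(II = 2, DD = 1),
                     ses = c(II = .2, DD = .2),
                     ns = c(II = 10, DD = 10), geno_freq_I = 0.5, seed = 71)
  expect_identical(nrow(association_scan(herd, "L1", character())), 0L)
  expect_error(association_scan(herd, "L1", "nope"), "unknown column")

  # one real effect among many null traits should rank first by p
  wins <- vapply(1:100, function(s) {
    cfg <- herd_config(300, sex_counts = c(female = 300),
                       loci = locus_spec("L1", "I", 0.5), seed = 3000 + s)
    h <- simulate_genotypes(cfg)
    h <- withr::with_seed(3000 + s, {
      for (k in 1:20) h[[paste0("null", k)]] <- rnorm(300, 5, 1)
      eff <- c(II = 0.6, ID = 0.3, DD = 0)
      h$signal <- 5 + eff[h$L1] + rnorm(300, 0, 1)
      h
    })
    res <- association_scan(h, "L1", c(paste0("null", 1:20), "signal"))
    first <- res[!duplicated(res$trait), ]
    first$trait[which.min(first$p)] == "signal"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("sex stratification keeps the null stratum calibrated", {
  rej <- vapply(1:100, function(s) {
    cfg <- herd_config(400, sex_counts = c(male = 200, female = 200),
                       loci = locus_spec("L1", "I", 0.5), seed = 11000 + s)
    h <- simulate_genotypes(cfg)
    h <- withr::with_seed(11000 + s, {
      eff <- c(II = 0.8, ID = 0.4, DD = 0)
      base <- rnorm(400, 5, 1)
      h$y <- ifelse(h$sex == "female", base + eff[h$L1], base)
      h
    })
    res <- association_scan(h, "L1", "y", stratify_by_sex = TRUE)
    male_p <- unique(res$p[res$stratum == "male"])
    male_p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)  # no enrichment beyond alpha + noise
})

test_that("BH column adjusts within stratum and preserves the raw p", {
  herd <- trait_herd(200, means = c(II = 2, DD = 1.9),
                     ses = c(II = .3, DD = .3),
                     ns = c(II = 10, DD = 10), geno_freq_I = 0.5, seed = 81)
  herd$y2 <- herd$y
  res <- association_scan(herd, "L1", c("y", "y2"), fdr = TRUE)
  expect_true(all(res$p_bh >= res$p - 1e-12, na.rm = TRUE))
})
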