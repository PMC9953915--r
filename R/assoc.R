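#' Assign compact-letter-display significance letters
#'
#' Implements the insert-and-absorb algorithm: groups are ordered by
#' descending mean; any pair not significantly different at `alpha` must
#' share a letter, any significantly different pair must not. Identical
#' patterns of threshold crossings yield identical letter patterns
#' regardless of input order.
#'
#' @param means Named numeric vector of group means.
#' @param p_matrix Symmetric matrix of pairwise p-values (dimnames matching
#'   `names(means)`); `NA` entries are treated as not significant.
#' @param alpha Significance threshold.
#' @param uppercase Emit `A`, `B`, ... instead of `a`, `b`, ....
#' @return Named character vector of letter strings, one per group. All
#'   groups share one letter when nothing is significant.
#' @export
assign_letters <- function(means, p_matrix, alpha = 0.05,
                           uppercase = FALSE) {
  ord <- names(sort(means, decreasing = TRUE))
  k <- length(ord)
  sig <- function(a, b) {
    p <- p_matrix[a, b]
    !is.na(p) && p < alpha
  }
  # columns = letters; membership matrix built by insert-and-absorb
  cols <- list(ord[1])
  for (g in ord[-1]) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      if (!any(vapply(cols[[ci]], sig, logical(1), b = g))) {
        cols[[ci]] <- c(cols[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      # new column seeded with g plus every earlier group not
      # significantly different from it
      compat <- ord[seq_len(match(g, ord) - 1)]
      compat <- compat[!vapply(compat, sig, logical(1), b = g)]
      cols[[length(cols) + 1]] <- c(compat, g)
    }
  }
  # absorb columns that are subsets of another
  keep <- rep(TRUE, length(cols))
  for (i in seq_along(cols)) for (j in seq_along(cols))
    if (i != j && keep[i] && keep[j] &&
        all(cols[[i]] %in% cols[[j]])) keep[i] <- FALSE
  cols <- cols[keep]
  letters_pool <- if (uppercase) LETTERS else letters
  out <- stats::setNames(rep("", k), ord)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters_pool[ci])
  out[names(means)]
}

#' Two-group t-test with a report-table row
#'
#' Independent-samples t-test between two genotype groups. The default is
#' the pooled-variance (classical equal-variance) test; Welch's unequal
#' variance form is available. Reports per-group n, mean and standard
#' error alongside the statistic.
#'
#' @param values_a,values_b Numeric trait values (kg) for the two groups,
#'   `NA` dropped; each group needs n >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @param labels Group labels for the output (default `"a"`, `"b"`).
#' @return List of class `assoc_test` with `groups` (data frame: group, n,
#'   mean, se, letters at 0.05 and 0.01), `statistic` (t), `df`, `p`,
#'   `method`. With zero variance in both groups and equal means, `t = 0`
#'   and `p = 1` by convention.
#' @export
t_test_two_groups <- function(values_a, values_b,
                              variant = c("pooled", "welch"),
                              labels = c("a", "b")) {
  variant <- match.arg(variant)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
               parameter = length(a) + length(b) - 2,
               p.value = if (equal) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = variant == "pooled")
  }
  p <- tt$p.value
  grp <- data.frame(
    group = labels,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    se = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))))
  pm <- matrix(p, 2, 2, dimnames = list(labels, labels)); diag(pm) <- NA
  means <- stats::setNames(grp$mean, labels)
  grp$letters_05 <- assign_letters(means, pm, 0.05)
  grp$letters_01 <- assign_letters(means, pm, 0.01, uppercase = TRUE)
  structure(list(groups = grp, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = p,
                 method = paste0(variant, " t-test")),
            class = "assoc_test")
}

#' One-way ANOVA across diplotype (or genotype) groups
#'
#' Fits a one-way fixed-effect ANOVA across the supplied groups. Groups
#' with fewer than 2 observations are reported but excluded from the
#' omnibus test and the pairwise comparisons. Pairwise significance
#' letters come from all pairwise pooled-variance t-tests at 0.05
#' (lowercase) and 0.01 (uppercase).
#'
#' @param groups Named list of numeric value vectors, one per group.
#' @return List of class `assoc_test` with `groups` (group, n, mean, se,
#'   tested flag, letters), `statistic` (F), `df` (numerator, denominator),
#'   `p`, `method`. With exactly two testable groups, `F = t^2` of the
#'   pooled t-test.
#' @export
anova_one_way <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  n <- lengths(groups)
  testable <- n >= 2
  if (sum(testable) < 2)
    stop("fewer than 2 groups with n >= 2: nothing to test", call. = FALSE)
  g <- groups[testable]
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), lengths(g)))
  fit <- stats::aov(y ~ f)
  an <- stats::anova(fit)
  grp <- data.frame(
    group = names(groups), n = n,
    mean = vapply(groups, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    se = vapply(groups, function(v) if (length(v) >= 2)
      stats::sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
    tested = testable, row.names = NULL)
  # pairwise pooled t-tests among testable groups
  tn <- names(g)
  pm <- matrix(NA_real_, length(tn), length(tn), dimnames = list(tn, tn))
  if (length(tn) >= 2)
    for (i in seq_along(tn)[-1]) for (j in seq_len(i - 1)) {
      pm[i, j] <- pm[j, i] <-
        stats::t.test(g[[i]], g[[j]], var.equal = TRUE)$p.value
    }
  means <- stats::setNames(grp$mean[testable], tn)
  l05 <- assign_letters(means, pm, 0.05)
  l01 <- assign_letters(means, pm, 0.01, uppercase = TRUE)
  grp$letters_05 <- ifelse(testable, l05[grp$group], "")
  grp$letters_01 <- ifelse(testable, l01[grp$group], "")
  structure(list(groups = grp, statistic = an$`F value`[1],
                 df = c(an$Df[1], an$Df[2]), p = an$`Pr(>F)`[1],
                 method = "one-way ANOVA"),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Fixed-effect genotype + sex linear model
#'
#' Fits the additive fixed-effect model `trait = mu + genotype + sex + e`
#' by ordinary least squares with reference-level (treatment) coding, and
#' reports per-effect F tests (marginal, each effect adjusted for the
#' other). Individuals of unrecorded sex or missing genotype/trait are
#' dropped; if sex (or genotype) is constant in the remaining data the
#' aliased term is dropped from the model and noted.
#'
#' @param pop Population data frame.
#' @param trait,locus Column names of the response and the genotype factor.
#' @return List of class `glm_result` with `coefficients`, `sigma2`
#'   (residual variance), `effects` (data frame: term, df, F, p),
#'   `dropped` (character vector of aliased terms), `n`, and the
#'   underlying `lm` fit.
#' @export
glm_fit <- function(pop, trait, locus) {
  stopifnot(trait %in% names(pop), locus %in% names(pop))
  d <- data.frame(y = pop[[trait]], genotype = pop[[locus]],
                  sex = pop$sex, stringsAsFactors = FALSE)
  d <- d[!is.na(d$y) & !is.na(d$genotype) & d$sex %in% c("male", "female"), ]
  if (nrow(d) < 3) stop("too few complete observations", call. = FALSE)
  d$genotype <- factor(d$genotype)
  d$sex <- factor(d$sex)
  dropped <- character()
  terms <- c("genotype", "sex")
  for (t in terms) if (nlevels(droplevels(d[[t]])) < 2) {
    dropped <- c(dropped, t)
  }
  use <- setdiff(terms, dropped)
  if (!length(use)) stop("both genotype and sex are constant", call. = FALSE)
  fml <- stats::reformulate(use, response = "y")
  fit <- stats::lm(fml, data = d)
  dr <- stats::drop1(fit, test = "F")
  eff <- data.frame(term = rownames(dr)[-1], df = dr$Df[-1],
                    F = dr$`F value`[-1], p = dr$`Pr(>F)`[-1],
                    row.names = NULL)
  structure(list(coefficients = stats::coef(fit),
                 sigma2 = stats::sigma(fit)^2,
                 effects = eff, dropped = dropped, n = nrow(d), fit = fit),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("Fixed-effect model (n = %d)%s\n", x$n,
              if (length(x$dropped))
                paste0("; dropped aliased term(s): ",
                       paste(x$dropped, collapse = ", ")) else ""))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Add a combined two-locus diplotype column
#'
#' @param pop Population data frame.
#' @param locus_a,locus_b Genotype columns.
#' @param name Name of the new column (default `"diplotype"`). Labels are
#'   `"<genoA>-<genoB>"`, e.g. `"DD-II"`; missing at either locus gives `NA`.
#' @return `pop` with the diplotype column appended.
#' @export
add_diplotype <- function(pop, locus_a, locus_b, name = "diplotype") {
  stopifnot(locus_a %in% names(pop), locus_b %in% names(pop))
  pop[[name]] <- ifelse(is.na(pop[[locus_a]]) | is.na(pop[[locus_b]]),
                        NA_character_,
                        paste0(pop[[locus_a]], "-", pop[[locus_b]]))
  pop
}

#' Scan trait x locus associations across the herd
#'
#' For every requested trait, grouping column (a locus or a diplotype
#' column) and stratum, splits trait values by group and tests: a pooled
#' t-test when exactly two groups have n >= 2, a one-way ANOVA when more
#' do. Groups below n = 2 are reported untested; groups with 2 <= n < 3
#' are flagged low-n. No multiple-testing correction is applied by
#' default; `fdr = TRUE` appends a Benjamini-Hochberg column per stratum.
#'
#' @param pop Population data frame.
#' @param loci Character vector of grouping columns to scan.
#' @param traits Character vector of trait columns (empty vector gives an
#'   empty result).
#' @param stratify_by_sex Run separately within males and females
#'   (individuals of unrecorded sex are excluded from stratified runs)?
#' @param fdr Append a BH-adjusted p column?
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return Long-format data frame: one row per trait x locus x stratum x
#'   group with columns `trait`, `locus`, `stratum`, `group`, `n`, `mean`,
#'   `se`, `letters_05`, `letters_01`, `low_n`, `test`, `statistic`, `df`,
#'   `p` (test columns repeated across the group rows; `NA` with a `note`
#'   when fewer than two testable groups exist).
#' @export
association_scan <- function(pop, loci, traits, stratify_by_sex = FALSE,
                             fdr = FALSE, variant = "pooled") {
  missing_cols <- setdiff(c(loci, traits), names(pop))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  strata <- if (stratify_by_sex) c("male", "female") else "all"
  out <- list()
  for (st in strata) {
    sub <- if (st == "all") pop else pop[pop$sex == st, ]
    for (locus in loci) for (trait in traits) {
      vals <- split(sub[[trait]][!is.na(sub[[trait]]) &
                                   !is.na(sub[[locus]])],
                    sub[[locus]][!is.na(sub[[trait]]) &
                                   !is.na(sub[[locus]])])
      vals <- vals[lengths(vals) > 0]
      row0 <- data.frame(trait = trait, locus = locus, stratum = st)
      n_testable <- sum(lengths(vals) >= 2)
      if (length(vals) == 0 || n_testable < 2) {
        g <- if (length(vals)) data.frame(
          group = names(vals), n = lengths(vals),
          mean = vapply(vals, mean, numeric(1)),
          se = vapply(vals, function(v) if (length(v) >= 2)
            stats::sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
          letters_05 = "", letters_01 = "", row.names = NULL)
        else data.frame(group = NA_character_, n = 0L, mean = NA_real_,
                        se = NA_real_, letters_05 = "", letters_01 = "")
        res <- cbind(row0, g, test = NA_character_, statistic = NA_real_,
                     df = NA_real_, p = NA_real_,
                     note = "fewer than 2 testable groups")
      } else if (n_testable == 2) {
        keep <- names(vals)[lengths(vals) >= 2]
        tt <- t_test_two_groups(vals[[keep[1]]], vals[[keep[2]]],
                                variant = variant, labels = keep)
        g <- tt$groups
        rest <- setdiff(names(vals), keep)
        if (length(rest))
          g <- rbind(g, data.frame(
            group = rest, n = lengths(vals[rest]),
            mean = vapply(vals[rest], mean, numeric(1)),
            se = NA_real_, letters_05 = "", letters_01 = "",
            row.names = NULL))
        res <- cbind(row0, g, test = "t",
                     statistic = tt$statistic, df = tt$df, p = tt$p,
                     note = "")
      } else {
        av <- anova_one_way(vals)
        g <- av$groups[, c("group", "n", "mean", "se",
                           "letters_05", "letters_01")]
        res <- cbind(row0, g, test = "anova", statistic = av$statistic,
                     df = av$df[1], p = av$p, note = "")
      }
      res$low_n <- res$n >= 2 & res$n < 3
      out[[length(out) + 1]] <- res
    }
  }
  if (!length(out))
    return(data.frame(trait = character(), locus = character(),
                      stratum = character(), group = character(),
                      n = integer(), mean = numeric(), se = numeric(),
                      letters_05 = character(), letters_01 = character(),
                      test = character(), statistic = numeric(),
                      df = numeric(), p = numeric(), note = character(),
                      low_n = logical()))
  res <- do.call(rbind, out)
  res <- res[order(res$stratum, res$locus, res$trait, res$group), ]
  rownames(res) <- NULL
  if (fdr) {
    # one p per trait x locus x stratum test; adjust within stratum
    key <- paste(res$trait, res$locus, res$stratum)
    idx_first <- which(!duplicated(key))
    adj_first <- rep(NA_real_, length(idx_first))
    st_first <- res$stratum[idx_first]
    p_first <- res$p[idx_first]
    for (st in unique(st_first)) {
      sel <- st_first == st & !is.na(p_first)
      adj_first[sel] <- stats::p.adjust(p_first[sel], method = "BH")
    }
    res$p_bh <- adj_first[match(key, key[idx_first])]
  }
  res
}
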