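#' Describe a biallelic InDel locus
#'
#' A locus is a two-allele insertion/deletion polymorphism with alleles
#' labelled `I` (insertion) and `D` (deletion). One allele is the rare
#' mutant; its population frequency drives both the genotype simulation and
#' the pooled-screening design (through the per-individual carrier
#' frequency estimate used to size pools).
#'
#' @param name Locus label, used as a column name in population tables.
#' @param mutant_allele Which allele is the rare mutant, `"I"` or `"D"`.
#' @param mutant_freq Population frequency of the mutant allele, in `[0,1]`.
#' @param carrier_est Estimated per-individual carrier frequency used for
#'   pool-size optimisation (probability an individual carries at least one
#'   mutant allele). Defaults to the Hardy-Weinberg carrier probability
#'   implied by `mutant_freq`.
#' @return An object of class `locus_spec`.
#' @examples
#' locus_spec("P1-Ins-4-bp", "I", 0.052, carrier_est = 0.02)
#' @export
locus_spec <- function(name, mutant_allele = c("I", "D"), mutant_freq,
                       carrier_est = NULL) {
  mutant_allele <- match.arg(mutant_allele)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stop_if_not_prob(mutant_freq, "mutant_freq", open = FALSE)
  if (is.null(carrier_est))
    carrier_est <- 1 - (1 - mutant_freq)^2
  structure(list(name = name, mutant_allele = mutant_allele,
                 mutant_freq = mutant_freq, carrier_est = carrier_est),
            class = "locus_spec")
}

#' Describe the per-genotype distribution of a carcass trait
#'
#' Trait values are drawn per genotype from a normal distribution whose
#' moments are given as mean, standard error and group size, the form in
#' which association tables report them. The population standard deviation
#' is recovered as `SE * sqrt(n)`.
#'
#' @param trait Trait label (e.g. `"beef_shoulder"`); values are in kg.
#' @param locus Name of the locus whose genotype determines the mean.
#' @param means,ses,ns Named numeric vectors (names are genotype labels such
#'   as `"II"`, `"ID"`) giving per-genotype mean, standard error of the mean,
#'   and the group size the SE was computed from. Genotypes absent from
#'   `means` receive no value.
#' @param sex Optional sex restriction (`"male"` or `"female"`); individuals
#'   of other or unknown sex get no value for this trait.
#' @param missing_rate Probability that an otherwise eligible individual is
#'   missing this trait, in `[0,1]`.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(trait, locus, means, ses, ns, sex = NULL,
                       missing_rate = 0) {
  stopifnot(is.character(trait), length(trait) == 1,
            is.character(locus), length(locus) == 1)
  g <- names(means)
  if (is.null(g) || !all(g %in% GENOTYPES))
    stop("`means` must be named with genotype labels from {II, ID, DD}",
         call. = FALSE)
  if (!setequal(g, names(ses)) || !setequal(g, names(ns)))
    stop("`means`, `ses` and `ns` must cover the same genotypes", call. = FALSE)
  ses <- ses[g]; ns <- ns[g]
  stopifnot(all(ses > 0), all(ns >= 2))
  if (!is.null(sex)) sex <- match.arg(sex, c("male", "female"))
  stop_if_not_prob(missing_rate, "missing_rate", open = FALSE)
  structure(list(trait = trait, locus = locus, means = means, ses = ses,
                 ns = ns, sex = sex, missing_rate = missing_rate),
            class = "trait_spec")
}

#' Configure a synthetic herd
#'
#' Bundles everything the herd generator needs: cohort size, the sex
#' composition, the two loci with their mutant-allele frequencies, the
#' target two-locus linkage disequilibrium (as D'), and the trait
#' distributions.
#'
#' @param n_individuals Cohort size.
#' @param sex_counts Named integer vector with entries `male`, `female`,
#'   `missing`, summing to `n_individuals`.
#' @param loci List of one or two [locus_spec()] objects.
#' @param d_prime Target normalised linkage disequilibrium D' in `[0,1]`
#'   between the two loci (ignored with a single locus).
#' @param coupling Phase of the disequilibrium: `"coupling"` places positive
#'   D between the two mutant alleles (mutants co-occur on haplotypes),
#'   `"repulsion"` the opposite. The phase is a free choice of the
#'   generator, not an estimate.
#' @param trait_specs List of [trait_spec()] objects.
#' @param seed Integer seed making the herd reproducible.
#' @return An object of class `herd_config`.
#' @seealso [sdbcgr_herd_config()] for a ready-made configuration emulating
#'   a 640-head black-cattle conservation herd.
#' @export
herd_config <- function(n_individuals,
                        sex_counts = c(male = 0, female = 0, missing = 0),
                        loci, d_prime = 0, coupling = c("coupling", "repulsion"),
                        trait_specs = list(), seed = 1L) {
  coupling <- match.arg(coupling)
  stopifnot(n_individuals >= 1)
  sexes <- c("male", "female", "missing")
  if (is.null(names(sex_counts)) || !all(names(sex_counts) %in% sexes))
    stop("`sex_counts` must be named with male/female/missing", call. = FALSE)
  full <- stats::setNames(rep(0L, 3), sexes)
  full[names(sex_counts)] <- as.integer(sex_counts)
  if (sum(full) != n_individuals)
    stop(sprintf("sex counts sum to %d, not n_individuals = %d",
                 sum(full), n_individuals), call. = FALSE)
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  stopifnot(length(loci) %in% 1:2,
            all(vapply(loci, inherits, logical(1), "locus_spec")))
  nm <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("locus names must be unique", call. = FALSE)
  stop_if_not_prob(d_prime, "d_prime", open = FALSE)
  stopifnot(all(vapply(trait_specs, inherits, logical(1), "trait_spec")))
  bad <- setdiff(vapply(trait_specs, `[[`, character(1), "locus"), nm)
  if (length(bad))
    stop("trait_specs reference unknown loci: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals), sex_counts = full,
                 loci = loci, d_prime = d_prime, coupling = coupling,
                 trait_specs = trait_specs, seed = as.integer(seed)),
            class = "herd_config")
}

#' Default herd configuration emulating the SDBCGR cohort
#'
#' A 640-individual herd (172 males, 466 females, 2 of unrecorded sex)
#' carrying two low-frequency InDel loci: an upstream 4-bp insertion with
#' mutant (I) allele frequency 0.052 and carrier estimate 0.02, and an
#' intronic 8-bp deletion with mutant (D) allele frequency 0.009 and carrier
#' estimate 0.01. The loci are generated in complete disequilibrium
#' (D' = 1) by default. Trait distributions follow the published
#' per-genotype means, SEs and group sizes for the female- and
#' male-restricted carcass traits; per-trait missingness is set so the
#' expected number of phenotyped individuals matches the reported group
#' sizes.
#'
#' @param seed Integer seed.
#' @param d_prime Target D' between the two loci.
#' @return A [herd_config()] object.
#' @export
sdbcgr_herd_config <- function(seed = 1L, d_prime = 1) {
  p1 <- locus_spec("P1", "I", 0.052, carrier_est = 0.02)
  p2 <- locus_spec("P2", "D", 0.009, carrier_est = 0.01)
  n_f <- 466; n_m <- 172
  tr <- function(trait, locus, id_m, id_se, id_n, ii_m, ii_se, ii_n,
                 sex = "female") {
    n_sex <- if (sex == "female") n_f else n_m
    trait_spec(trait, locus,
               means = c(ID = id_m, II = ii_m),
               ses = c(ID = id_se, II = ii_se),
               ns = c(ID = id_n, II = ii_n),
               sex = sex,
               missing_rate = max(0, 1 - (id_n + ii_n) / n_sex))
  }
  traits <- list(
    tr("beef_shoulder",        "P1", 1.30, 0.10,  29, 1.02, 0.02, 163),
    tr("tongue_root",          "P1", 1.53, 0.14,   4, 2.02, 0.05,  29),
    tr("back_tendon",          "P2", 0.55, 0.06,   6, 0.71, 0.01, 363),
    tr("money_tendon",         "P2", 1.06, 0.02,   6, 1.21, 0.01, 366),
    tr("thick_flank",          "P2", 9.47, 0.53,   6, 11.37, 0.11, 363),
    tr("beef_shin",            "P2", 14.17, 0.17,  6, 15.92, 0.28, 323),
    tr("triangle_thick_flank", "P2", 2.09, 0.10,   6, 2.53, 0.03, 367),
    tr("triangle_flank",       "P2", 3.79, 0.08,   6, 4.78, 0.05, 367),
    tr("rump",                 "P2", 3.90, 0.15,   6, 4.73, 0.04, 365),
    tr("small_tenderloin",     "P2", 2.00, 0.18,   6, 2.43, 0.03, 358),
    tr("brisket_fat",          "P2", 4.48, 0.96,   4, 3.36, 0.11,  82,
       sex = "male"))
  herd_config(640,
              sex_counts = c(male = n_m, female = n_f, missing = 2),
              loci = list(p1, p2), d_prime = d_prime,
              trait_specs = traits, seed = seed)
}

#' Read a herd configuration from a YAML or JSON file
#'
#' The document mirrors the [herd_config()] fields: `n_individuals`,
#' `sex_counts`, `loci` (each with `name`, `mutant_allele`, `mutant_freq`,
#' optional `carrier_est`), `d_prime`, `coupling`, `trait_specs` (each with
#' `trait`, `locus`, per-genotype `means`/`ses`/`ns`, optional `sex`,
#' `missing_rate`) and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [herd_config()] object.
#' @export
read_herd_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  as_num <- function(x) stats::setNames(as.numeric(unlist(x)),
                                        names(unlist(x)))
  loci <- lapply(raw$loci, function(l)
    locus_spec(l$name, l$mutant_allele, l$mutant_freq,
               carrier_est = l$carrier_est))
  traits <- lapply(raw$trait_specs %||% list(), function(t)
    trait_spec(t$trait, t$locus, as_num(t$means), as_num(t$ses),
               as_num(t$ns), sex = t$sex,
               missing_rate = t$missing_rate %||% 0))
  herd_config(raw$n_individuals, as_num(raw$sex_counts), loci,
              d_prime = raw$d_prime %||% 0,
              coupling = raw$coupling %||% "coupling",
              trait_specs = traits, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
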