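#' Write a population table to CSV
#'
#' Missing values are written as empty fields; columns are `id`, `sex`,
#' then genotype and trait columns.
#'
#' @param pop Population data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a genotype/phenotype table
#'
#' Expects a CSV with header containing `id` and `sex`; genotype columns
#' must contain only `II`, `ID`, `DD` or empty. Malformed genotype tokens
#' are rejected with their line number; duplicate ids are an error.
#'
#' @param path CSV path.
#' @param genotype_cols Names of the genotype columns. Default: every
#'   non-numeric column other than `id` and `sex`.
#' @return Population data frame (empty genotype fields become `NA`).
#' @export
read_genotype_table <- function(path, genotype_cols = NULL) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character")
  if (!all(c("id", "sex") %in% names(pop)))
    stop("table must have 'id' and 'sex' columns", call. = FALSE)
  if (anyDuplicated(pop$id))
    stop("duplicate id(s): ",
         paste(unique(pop$id[duplicated(pop$id)]), collapse = ", "),
         call. = FALSE)
  other <- setdiff(names(pop), c("id", "sex"))
  numericish <- vapply(other, function(cl) {
    v <- pop[[cl]][!is.na(pop[[cl]])]
    length(v) == 0 || !anyNA(suppressWarnings(as.numeric(v)))
  }, logical(1))
  if (is.null(genotype_cols)) genotype_cols <- other[!numericish]
  for (cl in genotype_cols) {
    v <- pop[[cl]]
    bad <- which(!is.na(v) & !v %in% GENOTYPES)
    if (length(bad))
      stop(sprintf("unknown genotype token '%s' in column '%s', line %d",
                   v[bad[1]], cl, bad[1] + 1L), call. = FALSE)
  }
  for (cl in setdiff(other, genotype_cols))
    pop[[cl]] <- as.numeric(pop[[cl]])
  bad_sex <- which(!is.na(pop$sex) & !pop$sex %in% c("male", "female",
                                                     "missing"))
  if (length(bad_sex))
    stop(sprintf("unknown sex token '%s', line %d",
                 pop$sex[bad_sex[1]], bad_sex[1] + 1L), call. = FALSE)
  pop$sex[is.na(pop$sex)] <- "missing"
  pop
}

#' Run the full screening-and-characterisation pipeline
#'
#' Chains the stages on one configuration: simulate the herd, design and
#' simulate pooled screening per locus, compute per-locus population
#' genetics and two-locus LD, and scan trait associations. Writes a
#' reproducible bundle: `herd.csv`, `me_design.json`,
#' `pool_outcome_<locus>.tsv`, `locus_stats.tsv`, `ld.json`,
#' `association.tsv`, `association_diplotype.tsv` and `manifest.json`.
#' Per-stage seeds are derived from the global seed by fixed offsets, so
#' an identical config and seed reproduce the bundle byte for byte.
#'
#' @param config A [herd_config()]; its loci carry the carrier-frequency
#'   estimates used for pool design.
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; defaults to the config's.
#' @param fp_rate,fn_rate Pool-level error rates for the screening
#'   simulation.
#' @param n_max Largest pool size scanned by the design.
#' @return Invisibly, a list with the stage results (`herd`, `designs`,
#'   `outcomes`, `locus_stats`, `ld`, `association`,
#'   `association_diplotype`) and `paths` of the written files.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         fp_rate = 0, fn_rate = 0, n_max = 64L) {
  stopifnot(inherits(config, "herd_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  paths <- character()
  config$seed <- as.integer(seed)

  herd <- simulate_herd(config)
  write_population_table(herd, pth("herd.csv"))
  paths <- c(paths, pth("herd.csv"))

  designs <- lapply(config$loci, function(l)
    optimal_pool_size(config$n_individuals, l$carrier_est,
                      n_max = min(n_max, config$n_individuals)))
  names(designs) <- vapply(config$loci, `[[`, character(1), "name")
  jsonlite::write_json(
    lapply(designs, function(d)
      d[c("N", "p", "n_opt", "expected_rt", "predicted_rt",
          "predicted_reduction")]),
    pth("me_design.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pth("me_design.json"))

  outcomes <- list()
  for (k in seq_along(config$loci)) {
    l <- config$loci[[k]]
    plan <- make_pools(herd$id, designs[[l$name]]$n_opt)
    out <- run_pools(plan, herd, l$name, l$mutant_allele,
                     fp_rate = fp_rate, fn_rate = fn_rate,
                     seed = seed + 100L + k)
    outcomes[[l$name]] <- out
    f <- pth(sprintf("pool_outcome_%s.tsv", l$name))
    utils::write.table(out$pools, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, f)
  }

  stats_tab <- locus_stats_table(herd, names(designs))
  utils::write.table(stats_tab, pth("locus_stats.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, pth("locus_stats.tsv"))

  ld <- NULL
  if (length(config$loci) == 2) {
    nm <- names(designs)
    ld <- em_haplotypes(two_locus_counts(herd, nm[1], nm[2]))
    jsonlite::write_json(
      list(haplotype_freqs = as.list(ld$haplotype_freqs),
           D = ld$D, D_prime = ld$D_prime, r2 = ld$r2,
           em_iterations = ld$em_iterations),
      pth("ld.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pth("ld.json"))
  }

  traits <- vapply(config$trait_specs, `[[`, character(1), "trait")
  assoc <- association_scan(herd, names(designs), unique(traits),
                            stratify_by_sex = TRUE)
  utils::write.table(assoc, pth("association.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, pth("association.tsv"))

  assoc_dip <- NULL
  if (length(config$loci) == 2) {
    nm <- names(designs)
    herd_d <- add_diplotype(herd, nm[1], nm[2])
    assoc_dip <- association_scan(herd_d, "diplotype", unique(traits),
                                  stratify_by_sex = TRUE)
    utils::write.table(assoc_dip, pth("association_diplotype.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, pth("association_diplotype.tsv"))
  }

  manifest <- list(
    seed = seed,
    n_individuals = config$n_individuals,
    sex_counts = as.list(config$sex_counts),
    loci = lapply(config$loci, unclass),
    d_prime = config$d_prime,
    coupling = config$coupling,
    n_traits = length(traits),
    fp_rate = fp_rate, fn_rate = fn_rate, n_max = n_max,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("indelscreen")))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, pth("manifest.json"))

  invisible(list(herd = herd, designs = designs, outcomes = outcomes,
                 locus_stats = stats_tab, ld = ld, association = assoc,
                 association_diplotype = assoc_dip, paths = paths))
}
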