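#' @keywords internal
"_PACKAGE"

GENOTYPES <- c("II", "ID", "DD")

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a single value in %s, got %s",
                        name, if (open) "(0,1)" else "[0,1]",
                        paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(x)
}

# dosage of the mutant allele (0/1/2) encoded as a genotype string, given
# which allele ("I" or "D") is the mutant
genotype_from_dosage <- function(dosage, mutant_allele) {
  ref <- if (mutant_allele == "I") "D" else "I"
  homo_mut <- paste0(mutant_allele, mutant_allele)
  homo_ref <- paste0(ref, ref)
  c(homo_ref, "ID", homo_mut)[dosage + 1L]
}

dosage_from_genotype <- function(genotype, mutant_allele) {
  n_mut <- vapply(strsplit(genotype, ""), function(a) sum(a == mutant_allele),
                  integer(1))
  n_mut[is.na(genotype)] <- NA_integer_
  n_mut
}
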