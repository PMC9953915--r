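# Small herd configurations used across test files.

two_locus_config <- function(n, p1 = 0.052, p2 = 0.009, d_prime = 1,
                             seed = 1L, coupling = "coupling") {
  herd_config(n, sex_counts = c(female = n),
              loci = list(locus_spec("L1", "I", p1),
                          locus_spec("L2", "D", p2)),
              d_prime = d_prime, coupling = coupling, seed = seed)
}

# female-only herd with one locus and one trait spec
trait_herd <- function(n, means, ses, ns, geno_freq_I = 0.3, seed = 1L,
                       missing_rate = 0) {
  cfg <- herd_config(n, sex_counts = c(female = n),
                     loci = locus_spec("L1", "I", geno_freq_I),
                     trait_specs = list(
                       trait_spec("y", "L1", means, ses, ns,
                                  sex = "female",
                                  missing_rate = missing_rate)),
                     seed = seed)
  simulate_herd(cfg)
}
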