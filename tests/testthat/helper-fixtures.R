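# Small programmatic fixtures shared across test files.

tiny_counts <- function(genes = 6L, samples = 4L, seed = 11L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(genes * samples, lambda = 50), genes, samples,
                dimnames = list(sprintf("g%02d", seq_len(genes)),
                                sprintf("s%02d", seq_len(samples))))
    attr(m, "kind") <- "counts"
    m
  })
}

write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Two-cohort scenario with planted TFs, used by several suites.
planted_scenario <- function(seed, n_tfs = 10L, active = c(TF001 = 2),
                             n_samples = 100L, n_genes = 1500L,
                             prevalence = 0.3, n_cohorts = 2L) {
  reg <- sim_regulons(n_tfs, 40, n_genes, seed = seed + 1L)
  cfg <- sim_config(n_cohorts = n_cohorts, n_samples = n_samples,
                    n_genes = n_genes, prevalence_high = prevalence,
                    active_tfs = active, seed = seed)
  list(regulons = reg, config = cfg,
       cohorts = simulate_cohorts(cfg, reg))
}
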