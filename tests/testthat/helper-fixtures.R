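# Small fixture builders used across test files.

rand_count_table <- function(n_genes = 50, tissues = c("MS", "MP", "MO", "SL"),
                             lambda = 30, libsize = 1e6) {
  m <- matrix(rpois(n_genes * length(tissues), lambda), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), tissues))
  count_table(m, setNames(rep(libsize, length(tissues)), tissues))
}

rand_calls <- function(n_genes = 40, tissues = c("MS", "MP", "MO", "SL"),
                       p = 0.5) {
  matrix(runif(n_genes * length(tissues)) < p, n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)), tissues))
}

# The synthetic experiment used for parameter-recovery checks: 2,000 genes,
# 100 planted specific (focal rate floored at 20 reads per million) and 100
# planted preferential at fold 8, Poisson counts at study-scale depths.
recovery_config <- function(seed = 101) {
  sim_config(n_genes = 2000, n_specific = 100, n_preferential = 100,
             preferential_fold = 8, dispersion = 0, specific_min_cpm = 20,
             seed = seed)
}
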