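# Shared fixtures, built in code. The larger simulation runs are memoised so
# several test files can reuse the same cohort without re-simulating.

fixture_env <- new.env(parent = emptyenv())

write_temp_fasta <- function(..., names = NULL) {
  seqs <- c(...)
  if (is.null(names)) names <- paste0("r", seq_along(seqs))
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), path)
  path
}

sbs11_like <- function() {
  read_signature(system.file("extdata", "sbs11_like_synthetic.tsv",
                             package = "duplexspectra"))
}

cpg_control <- function() {
  read_signature(system.file("extdata", "cpg_control_synthetic.tsv",
                             package = "duplexspectra"))
}

# A pure 5'-purine-G -> A spectrum: pyrimidine-centered C>T with 3' C or T
purG_spectrum <- function() {
  ch <- spectrum_channels()
  f <- stats::setNames(numeric(96), ch)
  ct <- grepl("\\[C>T\\]", ch)
  f[ct & endsWith(ch, "C")] <- 0.6 / 4
  f[ct & endsWith(ch, "T")] <- 0.4 / 4
  spectrum96(frequency = f)
}

# One simulated animal: simulate -> consensus -> place -> call -> unique
run_animal <- function(region, spectrum, n_molecules, mutation_rate,
                       per_base_error_rate, seed) {
  cfg <- simulation_config(
    spectrum, n_molecules = n_molecules, mutation_rate = mutation_rate,
    per_base_error_rate = per_base_error_rate, seed = seed
  )
  fq1 <- tempfile(fileext = ".fq")
  fq2 <- tempfile(fileext = ".fq")
  mols <- simulate_molecules(cfg, region)
  fam <- simulate_reads(mols, cfg, region, fq1, fq2)
  cons <- duplex_consensus(fq1, fq2)
  placed <- align_dcs_set(cons, list(region))
  calls <- call_mutations(pileup(placed, list(region)), list(region))
  um <- unique_mutations(calls)
  unlink(c(fq1, fq2))
  list(config = cfg, molecules = mols, families = fam, consensus = cons,
       placed = placed, calls = calls, unique = um)
}

# The reference cohort used by the end-to-end recovery checks: 8 animals on
# one reporter-scale target, SBS11-like generator spectrum.
cohort_fixture <- function() {
  if (!is.null(fixture_env$cohort)) return(fixture_env$cohort)
  region <- random_region(6382L, seed = 424242L)
  sbs <- sbs11_like()
  animals <- lapply(1:8, function(i) {
    run_animal(region, sbs, n_molecules = 500L, mutation_rate = 5e-3,
               per_base_error_rate = 1e-3, seed = 1000L + i)
  })
  fixture_env$cohort <- list(region = region, spectrum = sbs,
                             animals = animals)
  fixture_env$cohort
}

# Independent log-space tail-sum oracle for the binomial log-odds
logodds_oracle <- function(k, n, p) {
  logsumexp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  if (k / n > p) {
    lp <- logsumexp(dbinom(k:n, n, p, log = TRUE))
    (log1p(-exp(lp)) - lp) / log(10)
  } else if (k / n < p) {
    lp <- logsumexp(dbinom(0:k, n, p, log = TRUE))
    -(log1p(-exp(lp)) - lp) / log(10)
  } else 0
}
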