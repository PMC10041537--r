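make_fastq <- function(seqs, path, names = NULL) {
  if (is.null(names)) names <- paste0("r", seq_along(seqs))
  writeLines(as.vector(rbind(
    paste0("@", names), seqs, "+",
    vapply(nchar(seqs), function(w) strrep("I", w), character(1))
  )), path)
  path
}

tagged <- function(tag, payload) paste0(tag, "TGACT", payload)

test_that("canonical family key is orientation-invariant", {
  expect_equal(canonical_family_key("AAAA", "CCCC"),
               list(key = "AAAA-CCCC", strand = "top"))
  expect_equal(canonical_family_key("CCCC", "AAAA"),
               list(key = "AAAA-CCCC", strand = "bottom"))
  tie <- canonical_family_key("GGGG", "GGGG")
  expect_equal(tie$key, "GGGG-GGGG")
  expect_equal(tie$strand, "tie")
  expect_error(canonical_family_key("AAA", "CCCC"), "length mismatch")
})

test_that("group_families splits reads by canonical key and strand", {
  pay <- strrep("A", 137)
  A <- strrep("A", 12); B <- strrep("C", 12)
  f1 <- tempfile(); f2 <- tempfile()
  make_fastq(c(rep(tagged(A, pay), 3), rep(tagged(B, pay), 3)), f1)
  make_fastq(c(rep(tagged(B, pay), 3), rep(tagged(A, pay), 3)), f2)
  g <- group_families(f1, f2)
  fams <- unique(g$reads[c("key", "strand")])
  expect_equal(nrow(fams), 2L)
  expect_setequal(fams$strand, c("top", "bottom"))
  expect_equal(length(unique(fams$key)), 1L)
  unlink(c(f1, f2))
})

test_that("reads with corrupted spacers are excluded and counted", {
  pay <- strrep("G", 137)
  A <- strrep("A", 12); B <- strrep("C", 12)
  f1 <- tempfile(); f2 <- tempfile()
  make_fastq(c(tagged(A, pay), paste0(A, "TTTTT", pay)), f1)
  make_fastq(c(tagged(B, pay), tagged(B, pay)), f2)
  g <- group_families(f1, f2)
  expect_equal(unname(g$counts["malformed"]), 1L)
  expect_equal(unname(g$counts["pairs_dropped_unparseable"]), 1L)
  expect_equal(nrow(g$reads), 2L)
  unlink(c(f1, f2))
})

test_that("SSCS follows the plurality-with-threshold rule", {
  expect_equal(build_sscs(rep("ACGT", 3), min_family_size = 3), "ACGT")
  # 3A/2C at position 1: 0.6 < 0.7 -> N
  members <- c("ACGT", "ACGT", "ACGT", "CCGT", "CCGT")
  expect_equal(build_sscs(members, 3, 0.7), "NCGT")
  # family too small
  expect_null(build_sscs(c("ACGT", "ACGT"), min_family_size = 3))
  # exact tie -> N even at threshold 0.5
  expect_equal(build_sscs(c("AAAA", "AAAA", "CAAA", "CAAA"), 3, 0.5), "NAAA")
  expect_error(build_sscs(c("ACGT", "ACG"), 1), "unequal length")
})

test_that("SSCS matches a brute-force per-position tally oracle", {
  set.seed(77)
  for (rep_i in 1:300) {
    n <- sample(3:6, 1)
    L <- sample(5:12, 1)
    members <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1))
    thr <- sample(c(0.5, 0.7, 0.9), 1)
    got <- build_sscs(members, min_family_size = 1, consensus_threshold = thr)
    oracle <- vapply(seq_len(L), function(j) {
      tab <- table(substr(members, j, j))
      best <- names(tab)[tab == max(tab)]
      if (length(best) > 1 || max(tab) / n < thr) "N" else best
    }, character(1))
    expect_equal(got, paste(oracle, collapse = ""))
  }
})

test_that("DCS accepts only positions in perfect agreement", {
  d <- build_dcs("ACGT", "ACGT")
  expect_equal(d$sequence, "ACGT")
  expect_equal(d$n_masked, 0L)
  d <- build_dcs("ACGT", "ACTT")
  expect_equal(d$sequence, "ACNT")
  expect_equal(d$n_masked, 1L)
  d <- build_dcs("NCGT", "ACGT")
  expect_equal(d$sequence, "NCGT")
  expect_error(build_dcs("ACGT", "ACG"), "length mismatch")
})

test_that("pairing keeps duplexes and drops unpaired SSCS", {
  sscs <- data.frame(
    key = c("K", "K"), strand = c("top", "bottom"), mate = c(1L, 2L),
    sequence = c("ACGT", "ACGT"), stringsAsFactors = FALSE
  )
  p <- pair_and_filter(sscs)
  expect_equal(nrow(p$dcs), 1L)
  expect_equal(p$n_unpaired, 0L)

  solo <- pair_and_filter(sscs[1, , drop = FALSE])
  expect_equal(nrow(solo$dcs), 0L)
  expect_equal(solo$n_unpaired, 1L)
})

test_that("mask-trim keeps coordinates and the 111-nt informative window", {
  s <- strrep("A", 137)
  t <- trim_dcs(s)
  expect_equal(nchar(t), 137L)
  expect_equal(sum(strsplit(t, "")[[1]] != "N"), 111L)
  expect_equal(substr(t, 1, 8), strrep("N", 8))
  expect_equal(substr(t, 120, 137), strrep("N", 18))
  expect_equal(trim_dcs(s, list()), s)
  expect_error(trim_dcs("ACGT", list(c(1, 8))), "exceeds read length")
  expect_error(trim_dcs(s, list(c(1, 8), c(5, 20))), "overlapping")
})

test_that("family count on simulated reads matches the simulator truth", {
  reg <- random_region(1500L, seed = 31L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 40L,
                           mutation_rate = 0, per_base_error_rate = 0,
                           seed = 31L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  fam <- simulate_reads(mols, cfg, reg, f1, f2)
  g <- group_families(f1, f2)
  got <- nrow(unique(g$reads[c("key", "strand")]))
  want <- sum(fam$n_top > 0) + sum(fam$n_bottom > 0)
  expect_equal(got, want)
  unlink(c(f1, f2))
})

test_that("DCS count matches molecules with both strands at family minimum", {
  reg <- random_region(1500L, seed = 32L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 60L,
                           mutation_rate = 0, per_base_error_rate = 0,
                           seed = 32L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  fam <- simulate_reads(mols, cfg, reg, f1, f2)
  cons <- duplex_consensus(f1, f2, min_family_size = 3L)
  want <- 2L * sum(fam$n_top >= 3 & fam$n_bottom >= 3)
  expect_equal(unname(cons$report["dcs_built"]), want)
  # with no errors and no mutations nothing outside the trim is masked
  expect_true(all(vapply(cons$dcs$sequence, function(s)
    sum(strsplit(s, "")[[1]] == "N"), numeric(1)) == 26))
  unlink(c(f1, f2))
})

test_that("swapping tag roles across the dataset changes no DCS sequence", {
  reg <- random_region(1200L, seed = 33L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 25L,
                           mutation_rate = 5e-3, per_base_error_rate = 0,
                           seed = 33L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(mols, cfg, reg, f1, f2)
  cons_a <- duplex_consensus(f1, f2)
  # swapping read1 and read2 files swaps every pair's (alpha, beta) order
  cons_b <- duplex_consensus(f2, f1)
  a <- cons_a$dcs[order(cons_a$dcs$key, cons_a$dcs$sequence), ]
  b <- cons_b$dcs[order(cons_b$dcs$key, cons_b$dcs$sequence), ]
  expect_equal(a$key, b$key)
  expect_equal(a$sequence, b$sequence)
  unlink(c(f1, f2))
})

test_that("raising stringency never increases non-N DCS bases", {
  reg <- random_region(1200L, seed = 34L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 40L,
                           mutation_rate = 2e-3, per_base_error_rate = 5e-3,
                           seed = 34L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(mols, cfg, reg, f1, f2)
  non_n <- function(cons) sum(vapply(cons$dcs$sequence, function(s)
    sum(strsplit(s, "")[[1]] != "N"), numeric(1)))
  base <- non_n(duplex_consensus(f1, f2, min_family_size = 3,
                                 consensus_threshold = 0.7))
  stricter_fam <- non_n(duplex_consensus(f1, f2, min_family_size = 4,
                                         consensus_threshold = 0.7))
  stricter_thr <- non_n(duplex_consensus(f1, f2, min_family_size = 3,
                                         consensus_threshold = 0.9))
  expect_lte(stricter_fam, base)
  expect_lte(stricter_thr, base)
  unlink(c(f1, f2))
})
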