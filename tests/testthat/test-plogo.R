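test_that("binomial log-odds matches the log-space tail-sum oracle", {
  set.seed(61)
  grid_n <- sample(1:200, 60, replace = TRUE)
  for (n in grid_n) {
    k <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.99)
    expect_equal(binomial_logodds(k, n, p), logodds_oracle(k, n, p),
                 tolerance = 1e-9)
  }
  # boundary and sign conventions
  expect_equal(binomial_logodds(1, 1, 0.5), 0)
  expect_equal(binomial_logodds(8, 10, 0.25), 3.3809328, tolerance = 1e-6)
  expect_lt(binomial_logodds(0, 50, 0.3), 0)
  expect_error(binomial_logodds(1, 10, 0), "p must be")
  expect_error(binomial_logodds(11, 10, 0.5), "0 <= k <= n")
})

test_that("extreme tails stay finite and monotone without capping", {
  h <- binomial_logodds(c(500, 900, 1000), 1000, 0.25)
  expect_true(all(is.finite(h)))
  expect_true(all(diff(h) > 0))
  expect_gt(h[3], 100)   # deep tail, far beyond any threshold
})

test_that("Bonferroni threshold reproduces 3.05 for 14 positions x 4 bases", {
  expect_equal(round(bonferroni_threshold(0.05, 14, 4), 2), 3.05)
  # single test: plain log-odds of alpha
  expect_equal(bonferroni_threshold(0.3, 1, 1), log10(0.7 / 0.3))
  # threshold grows with the number of tests
  ths <- vapply(c(1, 4, 14, 56, 200), function(m)
    bonferroni_threshold(0.05, m, 4), numeric(1))
  expect_true(all(diff(ths) > 0))
  expect_error(bonferroni_threshold(0), "alpha")
})

test_that("foreground windows are strand-normalized around the fixed base", {
  #             0123456789012345678
  reg <- reference_region("r", "AAACCCCGGGGTTTTACGT")
  muts <- data.frame(
    region = "r", pos = c(8L, 6L, 2L), ref = c("G", "C", "A"),
    alt = c("A", "T", "C"), stringsAsFactors = FALSE
  )
  fg <- extract_foreground_windows(muts, list(reg), "G", "A", flank = 2L)
  # G->A at 8 used as-is; C->T at 6 is G->A on the minus strand
  expect_equal(fg$n, 2L)
  expect_equal(fg$windows[1], substr(reg$sequence, 7, 11))
  expect_equal(fg$windows[2], revcomp(substr(reg$sequence, 5, 9)))
  expect_true(all(substr(fg$windows, 3, 3) == "G"))

  # a mutation too close to the end is skipped and counted
  edge <- data.frame(region = "r", pos = 1L, ref = "A", alt = "G")
  fg2 <- extract_foreground_windows(edge, list(reg), "A", "G", flank = 7L)
  expect_equal(fg2$n, 0L)
  expect_equal(fg2$n_skipped, 1L)
})

test_that("background windows cover both strands and subsample with a seed", {
  reg <- reference_region("r", "TTTTGTTTTTTCTTTT")
  bg <- extract_background_windows(list(reg), "G", flank = 2L)
  # one G (fwd) and one C (G on the minus strand)
  expect_equal(bg$n, 2L)
  expect_true(all(substr(bg$windows, 3, 3) == "G"))
  expect_setequal(bg$windows, c("TTGTT", revcomp("TTCTT")))

  big <- random_region(2000L, seed = 62L)
  all_w <- extract_background_windows(list(big), "G", flank = 7L)
  # brute-force occurrence count: every interior G or C with full flanks
  chars <- strsplit(big$sequence, "")[[1]]
  inner <- chars[8:(big$length - 7)]
  expect_equal(all_w$n, sum(inner %in% c("G", "C")))

  s1 <- extract_background_windows(list(big), "G", 7L, sample_size = 100,
                                   seed = 7L)
  s2 <- extract_background_windows(list(big), "G", 7L, sample_size = 100,
                                   seed = 7L)
  expect_equal(s1$windows, s2$windows)
  expect_equal(s1$n, 100L)
  expect_error(extract_background_windows(
    list(reference_region("x", "AAAA")), "G"), "no occurrences")
})

test_that("plogo heights follow the binomial model and flag significance", {
  set.seed(63)
  bgw <- vapply(1:400, function(i)
    paste(c(sample(c("A", "C", "G", "T"), 7, TRUE), "G",
            sample(c("A", "C", "G", "T"), 7, TRUE)), collapse = ""),
    character(1))
  bg <- structure(list(windows = bgw, n = length(bgw), n_skipped = 0L,
                       role = "background", center = "G", flank = 7L),
                  class = "context_windows")
  # foreground: always T at position -1, otherwise drawn from background
  fgw <- vapply(sample(bgw, 100, TRUE), function(w) {
    substr(w, 7, 7) <- "T"
    w
  }, character(1), USE.NAMES = FALSE)
  fg <- structure(list(windows = fgw, n = length(fgw), n_skipped = 0L,
                       role = "foreground", center = "G", flank = 7L),
                  class = "context_windows")
  res <- plogo_matrix(fg, bg)
  tab <- res$table
  expect_equal(nrow(tab), 14L * 4L)
  cell <- tab[tab$position == -1 & tab$base == "T", ]
  expect_equal(cell$k, 100L)
  expect_equal(cell$frequency_pct, 100)
  expect_equal(cell$height,
               binomial_logodds(100, 100, cell$p), tolerance = 1e-12)
  expect_true(cell$significant)
  expect_gt(cell$height, res$threshold)
  # the fixed position is absent from the table
  expect_false(any(tab$position == 0))
  # significance flag is exactly the threshold rule
  expect_equal(tab$significant, abs(tab$height) >= res$threshold)
})

test_that("swapping foreground and background flips every height's sign", {
  set.seed(64)
  mkwin <- function(n, bias) vapply(seq_len(n), function(i) {
    w <- sample(c("A", "C", "G", "T"), 15, TRUE, prob = bias)
    w[8] <- "G"
    paste(w, collapse = "")
  }, character(1))
  a <- structure(list(windows = mkwin(300, c(0.4, 0.2, 0.2, 0.2)), n = 300L,
                      n_skipped = 0L, role = "foreground", center = "G",
                      flank = 7L), class = "context_windows")
  b <- structure(list(windows = mkwin(300, c(0.1, 0.3, 0.3, 0.3)), n = 300L,
                      n_skipped = 0L, role = "background", center = "G",
                      flank = 7L), class = "context_windows")
  hab <- plogo_matrix(a, b)$table$height
  hba <- plogo_matrix(b, a)$table$height
  expect_true(all(sign(hab) == -sign(hba) | (hab == 0 & hba == 0)))
})

test_that("null foreground drawn from the background is rarely significant", {
  reg <- random_region(4000L, seed = 65L)
  bg <- extract_background_windows(list(reg), "G", flank = 7L)
  set.seed(66)
  n_sig <- vapply(1:50, function(i) {
    # null unique mutations hit distinct sites: sample without replacement
    fgw <- sample(bg$windows, 600, replace = FALSE)
    fg <- structure(list(windows = fgw, n = 600L, n_skipped = 0L,
                         role = "foreground", center = "G", flank = 7L),
                    class = "context_windows")
    sum(plogo_matrix(fg, bg)$table$significant)
  }, numeric(1))
  expect_gte(mean(n_sig == 0), 0.95)
  # and across seeds the familywise cell fraction stays below alpha
  expect_lte(mean(n_sig) / 56, 0.05)
})

test_that("purine-before-G enrichment is recovered from injected mutations", {
  reg <- random_region(6382L, seed = 67L)
  cfg <- simulation_config(purG_spectrum(), n_molecules = 1500L,
                           mutation_rate = 3e-3, seed = 68L)
  mols <- simulate_molecules(cfg, reg)
  muts <- unique(mols$mutations[c("pos", "ref", "alt")])
  muts$region <- reg$name
  fg <- extract_foreground_windows(muts, list(reg), "G", "A", flank = 7L)
  expect_gt(fg$n, 800)
  bg <- extract_background_windows(list(reg), "G", flank = 7L)
  res <- plogo_matrix(fg, bg)
  g1 <- res$table[res$table$position == -1 & res$table$base == "G", ]
  a1 <- res$table[res$table$position == -1 & res$table$base == "A", ]
  expect_true(g1$significant && g1$height > 0)
  expect_true(a1$significant && a1$height > 0)
  # pyrimidines at -1 are correspondingly depleted
  t1 <- res$table[res$table$position == -1 & res$table$base == "T", ]
  expect_lt(t1$height, 0)
})
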