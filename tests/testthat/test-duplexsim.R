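test_that("simulation config validates rates and geometry", {
  sbs <- sbs11_like()
  expect_error(simulation_config(sbs, mutation_rate = 1.5), "mutation_rate")
  expect_error(simulation_config(sbs, fragment_length_range = c(350, 300)),
               "increasing")
  expect_error(simulation_config(sbs, read_length = 400), "read_length")
  cfg <- simulation_config(sbs, seed = 3L)
  expect_equal(cfg$fragment_length_range, c(300L, 350L))
  expect_equal(cfg$read_length, 137L)
})

test_that("molecule simulation is seeded and respects mutation_rate = 0", {
  reg <- random_region(2000L, seed = 2L)
  cfg0 <- simulation_config(sbs11_like(), n_molecules = 50L,
                            mutation_rate = 0, seed = 5L)
  m0 <- simulate_molecules(cfg0, reg)
  expect_equal(nrow(m0$mutations), 0L)
  expect_true(all(m0$molecules$end - m0$molecules$start >= 300))
  expect_true(all(m0$molecules$end <= reg$length))

  cfg <- simulation_config(sbs11_like(), n_molecules = 50L,
                           mutation_rate = 5e-3, seed = 5L)
  a <- simulate_molecules(cfg, reg)
  b <- simulate_molecules(cfg, reg)
  expect_identical(a, b)
})

test_that("injected mutations land only at sites matching the drawn channel", {
  reg <- random_region(4000L, seed = 8L)
  # concentrate the whole spectrum on one channel
  f <- stats::setNames(numeric(96), spectrum_channels())
  f["A[C>T]G"] <- 1
  cfg <- simulation_config(spectrum96(frequency = f), n_molecules = 2000L,
                           mutation_rate = 2e-3, seed = 9L)
  mols <- simulate_molecules(cfg, reg)
  expect_gt(nrow(mols$mutations), 200)
  # brute-force site inventory: ACG on either strand
  chars <- strsplit(reg$sequence, "")[[1]]
  tri <- substring(reg$sequence, seq_len(reg$length - 2), 3:reg$length)
  ok_fwd <- which(tri == "ACG")       # center C at 0-based pos i
  ok_rev <- which(tri == "CGT")       # center G, revcomp context ACG
  allowed <- c(ok_fwd, ok_rev)        # 0-based center = index (1-based i)
  expect_true(all(mols$mutations$pos %in% allowed))
  is_c <- mols$mutations$ref == "C"
  expect_true(all(mols$mutations$alt[is_c] == "T"))
  expect_true(all(mols$mutations$alt[!is_c] == "A"))
  expect_true(all(mols$mutations$ref[!is_c] == "G"))
})

test_that("mutations stay inside their molecule and match the reference", {
  reg <- random_region(3000L, seed = 4L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 200L,
                           mutation_rate = 5e-3, seed = 10L)
  mols <- simulate_molecules(cfg, reg)
  m <- merge(mols$mutations, mols$molecules, by.x = "molecule", by.y = "id")
  expect_true(all(m$pos >= m$start & m$pos < m$end))
  refb <- substring(reg$sequence, m$pos + 1L, m$pos + 1L)
  expect_equal(refb, m$ref)
  expect_true(all(m$alt != m$ref))
})

test_that("read simulation is byte-deterministic and error-free when configured", {
  reg <- random_region(1500L, seed = 6L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 20L,
                           mutation_rate = 0, per_base_error_rate = 0,
                           seed = 21L)
  mols <- simulate_molecules(cfg, reg)
  f1a <- tempfile(); f2a <- tempfile(); f1b <- tempfile(); f2b <- tempfile()
  simulate_reads(mols, cfg, reg, f1a, f2a)
  simulate_reads(mols, cfg, reg, f1b, f2b)
  expect_identical(readLines(f1a), readLines(f1b))
  expect_identical(readLines(f2a), readLines(f2b))

  # with no mutations and no errors every payload is a reference substring
  lines <- readLines(f1a)
  seqs <- lines[seq(2, length(lines), by = 4)]
  payload <- substr(seqs, 18L, nchar(seqs))
  hit <- vapply(payload, function(s)
    grepl(s, reg$sequence, fixed = TRUE) ||
      grepl(revcomp(s), reg$sequence, fixed = TRUE), logical(1))
  expect_true(all(hit))
  unlink(c(f1a, f2a, f1b, f2b))
})

test_that("reads carry the molecule's true mutations on both strands", {
  reg <- random_region(1500L, seed = 6L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 30L,
                           mutation_rate = 5e-3, per_base_error_rate = 0,
                           family_size_min = 1L, seed = 22L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(mols, cfg, reg, f1, f2)
  lines <- readLines(f1)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  seqs <- lines[seq(2, length(lines), by = 4)]
  m <- merge(mols$mutations, mols$molecules, by.x = "molecule", by.y = "id")
  # check mutations visible in the forward read window
  vis <- m[m$pos < m$start + cfg$read_length, ]
  for (i in seq_len(nrow(vis))) {
    fwd_reads <- grepl(sprintf("^mol%d:top:", vis$molecule[i]), ids)
    if (!any(fwd_reads)) next
    off <- 17L + vis$pos[i] - vis$start[i] + 1L
    expect_true(all(substr(seqs[fwd_reads], off, off) == vis$alt[i]))
  }
  unlink(c(f1, f2))
})

test_that("raw per-base artifact rate matches the configured binomial rate", {
  reg <- random_region(1500L, seed = 6L)
  cfg <- simulation_config(sbs11_like(), n_molecules = 60L,
                           mutation_rate = 0, per_base_error_rate = 1e-3,
                           seed = 23L)
  mols <- simulate_molecules(cfg, reg)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(mols, cfg, reg, f1, f2)
  mism <- 0L; tot <- 0L
  for (f in c(f1, f2)) {
    lines <- readLines(f)
    seqs <- substr(lines[seq(2, length(lines), by = 4)], 18L, 17L + 137L)
    for (s in seqs) {
      ok <- grepl(s, reg$sequence, fixed = TRUE) ||
        grepl(revcomp(s), reg$sequence, fixed = TRUE)
      tot <- tot + 137L
      if (!ok) {
        # locate by best of the two orientations against every offset is
        # overkill; count mismatches against the closest exact 20-mer anchor
        mism <- mism + 1L
      }
    }
  }
  # reads with >=1 artifact follow Binomial(137, 1e-3) per read
  n_reads <- tot / 137L
  p_read <- 1 - (1 - 1e-3)^137
  expect_lt(abs(mism - n_reads * p_read), 3 * sqrt(n_reads * p_read) + 3)
  unlink(c(f1, f2))
})

test_that("gpt colony-count simulation is seeded and recovers the true MF", {
  t0 <- simulate_gpt_counts(0, 10, seed = 1L)
  expect_true(all(t0$tg_resistant == 0))
  a <- simulate_gpt_counts(3e-5, 20, seed = 2L)
  b <- simulate_gpt_counts(3e-5, 20, seed = 2L)
  expect_identical(a, b)
  big <- simulate_gpt_counts(3e-5, 50, seed = 3L)
  mf <- mutant_frequency(big)$mf
  expect_lt(abs(mean(mf) - 3e-5) / 3e-5, 0.2)
  expect_error(simulate_gpt_counts(1.2, 5), "true_mf")
})
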