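DUPLEX_SPACER <- "TGACT"

#' Configure the synthetic duplex-read generator
#'
#' The generator emulates the study design the package targets: a ~6.4 kb
#' reporter target sheared to 300-350 bp fragments, duplex-tagged libraries
#' with 12-nt tags on each arm, 137 consensus-visible nt per read end, true
#' mutations injected per a 96-channel spectrum, and independent per-strand
#' artifacts that double-strand consensus must suppress.
#'
#' @param spectrum `spectrum96` used as the sampling distribution for true
#'   mutations.
#' @param n_molecules Number of duplex source molecules.
#' @param mutation_rate Expected true mutations per molecule-base.
#' @param fragment_length_range Integer pair; fragment lengths are uniform in
#'   this range (default 300-350 bp, the sonication target).
#' @param read_length Consensus-visible nt per read end (default 137).
#' @param family_size_mean Mean reads per strand family (Poisson, default 5).
#' @param family_size_min Lower truncation of the family-size draw (default 0,
#'   so a strand can yield no reads and leave its partner SSCS unpaired).
#' @param per_base_error_rate Strand-level artifact probability per read base
#'   (default 1e-3).
#' @param tag_length Duplex tag length per arm (default 12).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(spectrum,
                              n_molecules = 1000L,
                              mutation_rate = 1e-4,
                              fragment_length_range = c(300L, 350L),
                              read_length = 137L,
                              family_size_mean = 5,
                              family_size_min = 0L,
                              per_base_error_rate = 1e-3,
                              tag_length = 12L,
                              seed = 1L) {
  stopifnot(inherits(spectrum, "spectrum96"))
  if (is.null(spectrum$frequency) && sum(spectrum$counts) == 0) {
    stop("spectrum must carry frequencies or counts")
  }
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0, 1]")
  if (per_base_error_rate < 0 || per_base_error_rate > 1) {
    stop("per_base_error_rate must be in [0, 1]")
  }
  fragment_length_range <- as.integer(fragment_length_range)
  if (length(fragment_length_range) != 2L ||
      fragment_length_range[1] > fragment_length_range[2]) {
    stop("fragment_length_range must be an increasing integer pair")
  }
  if (read_length > fragment_length_range[1]) {
    stop("read_length must not exceed the minimum fragment length")
  }
  if (tag_length < 4L) stop("tag_length must be >= 4")
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  structure(
    list(
      spectrum = spectrum, n_molecules = as.integer(n_molecules),
      mutation_rate = mutation_rate,
      fragment_length_range = fragment_length_range,
      read_length = as.integer(read_length),
      family_size_mean = family_size_mean,
      family_size_min = as.integer(family_size_min),
      per_base_error_rate = per_base_error_rate,
      tag_length = as.integer(tag_length), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a random reference region
#'
#' Seeded uniform-composition DNA, used as a synthetic stand-in for a
#' reporter target region.
#'
#' @param length Region length in nt (default 6382, a reporter-scale target).
#' @param seed Integer seed.
#' @param name Region name.
#' @return A `reference_region`.
#' @export
random_region <- function(length = 6382L, seed = 1L, name = "synthetic_target") {
  set.seed(seed)
  reference_region(name, paste(sample(DNA_BASES, length, replace = TRUE),
                               collapse = ""))
}

# Positions (0-based, interior) matching each pyrimidine-centered context.
# A position matches a channel when its reference trinucleotide equals the
# channel context on either strand.
context_site_inventory <- function(region) {
  L <- region$length
  pos <- seq_len(L - 2L)           # 0-based interior positions
  tri <- substring(region$sequence, pos, pos + 2L)
  center_pyr <- substr(tri, 2, 2) %in% c("C", "T")
  key <- tri
  key[!center_pyr] <- revcomp(tri[!center_pyr])
  split(pos, key)
}

r_family_size <- function(n, mean, min) {
  x <- rpois(n, mean)
  while (any(x < min)) {
    x[x < min] <- rpois(sum(x < min), mean)
  }
  x
}

#' Simulate duplex source molecules with injected true mutations
#'
#' Fragment intervals are uniform over valid starts with lengths uniform in
#' the configured range. The number of true mutations per molecule is
#' Binomial(length, mutation_rate); each mutation's channel is drawn from the
#' configured spectrum and a concrete site drawn uniformly among the interior
#' reference positions inside the fragment whose trinucleotide context matches
#' that channel (on either strand). Channels with spectrum mass but no
#' matching site anywhere in the region trigger a warning and are
#' renormalized away.
#'
#' @param config A `simulation_config`.
#' @param region A `reference_region` longer than the maximum fragment.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `true_molecules` object: `$molecules` (id, region, start, end,
#'   strand) and `$mutations` (molecule, pos, ref, alt), positions 0-based.
#' @export
simulate_molecules <- function(config, region, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(region, "reference_region"))
  if (region$length <= config$fragment_length_range[2]) {
    stop("region must be longer than the maximum fragment length")
  }
  set.seed(seed)
  n <- config$n_molecules
  fl <- config$fragment_length_range
  lens <- if (fl[1] == fl[2]) rep(fl[1], n) else
    sample(seq(fl[1], fl[2]), n, replace = TRUE)
  starts <- vapply(region$length - lens + 1L,
                   function(m) sample.int(m, 1L) - 1L, integer(1))
  ends <- starts + lens

  prob <- spectrum_freq(config$spectrum)
  channels <- spectrum_channels()
  inventory <- context_site_inventory(region)
  ctx <- channel_trinuc(channels)
  have_sites <- ctx %in% names(inventory)
  dead <- prob > 0 & !have_sites
  if (any(dead)) {
    warning(sum(dead), " channel(s) with spectrum mass have no matching site",
            " in region '", region$name, "'; renormalizing")
    prob[dead] <- 0
  }
  if (sum(prob) <= 0) stop("no spectrum channel has matching sites in region")
  prob <- prob / sum(prob)

  k <- rbinom(n, lens, config$mutation_rate)
  mut_mol <- integer(0); mut_pos <- integer(0)
  mut_ref <- character(0); mut_alt <- character(0)
  seq_chars <- strsplit(region$sequence, "")[[1]]
  active <- which(prob > 0)
  for (i in which(k > 0)) {
    placed <- integer(0)
    for (j in seq_len(k[i])) {
      for (try in 1:50) {
        ch_idx <- active[sample.int(length(active), 1L,
                                    prob = prob[active])]
        sites <- inventory[[ctx[ch_idx]]]
        lo <- findInterval(starts[i] - 0.5, sites) + 1L
        hi <- findInterval(ends[i] - 0.5, sites)
        if (hi < lo) next
        p <- sites[lo + sample.int(hi - lo + 1L, 1L) - 1L]
        if (p %in% placed) next
        refb <- seq_chars[p + 1L]
        altb <- channel_alt(channels[ch_idx])
        if (refb %in% c("A", "G")) altb <- complement_base(altb)
        placed <- c(placed, p)
        mut_mol <- c(mut_mol, i); mut_pos <- c(mut_pos, p)
        mut_ref <- c(mut_ref, refb); mut_alt <- c(mut_alt, altb)
        break
      }
    }
  }
  structure(
    list(
      molecules = data.frame(
        id = seq_len(n), region = region$name, start = starts, end = ends,
        strand = "+", stringsAsFactors = FALSE
      ),
      mutations = data.frame(
        molecule = mut_mol, pos = mut_pos, ref = mut_ref, alt = mut_alt,
        stringsAsFactors = FALSE
      ),
      region = region$name
    ),
    class = "true_molecules"
  )
}

#' @export
print.true_molecules <- function(x, ...) {
  cat(sprintf("<true_molecules> %d molecules on %s, %d injected mutations\n",
              nrow(x$molecules), x$region, nrow(x$mutations)))
  invisible(x)
}

random_tags <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs[1])
  nerr <- rbinom(length(seqs), L, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(L, nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

write_fastq <- function(seqs, names, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(
    vapply(nchar(seqs), function(w) strrep("I", w), character(1))
  ))
  qs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Simulate duplex-tagged paired-end reads
#'
#' For each molecule a duplex tag pair (alpha, beta) is drawn. Top-strand
#' read pairs carry the tags in alpha-beta order (alpha on read 1), bottom
#' strand reads in beta-alpha order, so complementary families are
#' recognizable by tag-order swap. Bottom-strand reads are sequenced from the
#' opposite physical strand and therefore come out reverse-complemented with
#' respect to reference coordinates (flagged in the read header). Every read
#' carries the molecule's true mutations; independent per-base artifacts are
#' added at the configured rate. The tag is prepended in-sequence followed by
#' a fixed 5-nt spacer.
#'
#' @param molecules A `true_molecules` object.
#' @param config The `simulation_config`.
#' @param region The `reference_region` the molecules came from.
#' @param fastq1,fastq2 Output paths for read 1 / read 2.
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Invisibly, a data frame of per-molecule family sizes
#'   (`n_top`, `n_bottom`) plus tag assignments.
#' @export
simulate_reads <- function(molecules, config, region, fastq1, fastq2,
                           seed = config$seed + 1L) {
  stopifnot(inherits(molecules, "true_molecules"))
  set.seed(seed)
  mols <- molecules$molecules
  muts <- molecules$mutations
  n <- nrow(mols)
  RL <- config$read_length
  alpha <- random_tags(n, config$tag_length)
  beta <- random_tags(n, config$tag_length)
  clash <- alpha == beta
  while (any(clash)) {
    beta[clash] <- random_tags(sum(clash), config$tag_length)
    clash <- alpha == beta
  }
  n_top <- r_family_size(n, config$family_size_mean, config$family_size_min)
  n_bot <- r_family_size(n, config$family_size_mean, config$family_size_min)

  r1 <- vector("list", n); r2 <- vector("list", n); nm <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_top[i] + n_bot[i] == 0L) next
    s <- mols$start[i]; e <- mols$end[i]
    frag <- substr(region$sequence, s + 1L, e)
    mi <- muts[muts$molecule == mols$id[i], , drop = FALSE]
    if (nrow(mi)) {
      for (j in seq_len(nrow(mi))) {
        off <- mi$pos[j] - s + 1L
        substr(frag, off, off) <- mi$alt[j]
      }
    }
    fwd <- substr(frag, 1L, RL)
    rev <- revcomp(substr(frag, e - s - RL + 1L, e - s))
    pre_a <- paste0(alpha[i], DUPLEX_SPACER)
    pre_b <- paste0(beta[i], DUPLEX_SPACER)
    r1[[i]] <- c(rep(paste0(pre_a, fwd), n_top[i]),
                 rep(paste0(pre_b, rev), n_bot[i]))
    r2[[i]] <- c(rep(paste0(pre_b, rev), n_top[i]),
                 rep(paste0(pre_a, fwd), n_bot[i]))
    nm[[i]] <- c(
      if (n_top[i] > 0L) sprintf("mol%d:top:%d", mols$id[i], seq_len(n_top[i])),
      if (n_bot[i] > 0L) sprintf("mol%d:bottom:%d", mols$id[i],
                                 seq_len(n_bot[i]))
    )
  }
  r1 <- unlist(r1); r2 <- unlist(r2); nm <- unlist(nm)
  r1 <- apply_read_errors(r1, config$per_base_error_rate)
  r2 <- apply_read_errors(r2, config$per_base_error_rate)
  write_fastq(r1, paste0(nm, "/1"), fastq1)
  write_fastq(r2, paste0(nm, "/2"), fastq2)
  invisible(data.frame(
    id = mols$id, tag_alpha = alpha, tag_beta = beta,
    n_top = n_top, n_bottom = n_bot, stringsAsFactors = FALSE
  ))
}

#' Write the simulation truth table
#'
#' One row per molecule: id, interval, and the injected mutations encoded as
#' `pos:ref>alt` (0-based, semicolon-separated).
#'
#' @param molecules A `true_molecules`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(molecules, path) {
  mols <- molecules$molecules
  muts <- molecules$mutations
  enc <- vapply(mols$id, function(i) {
    mi <- muts[muts$molecule == i, , drop = FALSE]
    if (!nrow(mi)) return("")
    paste(sprintf("%d:%s>%s", mi$pos, mi$ref, mi$alt), collapse = ";")
  }, character(1))
  df <- cbind(mols, mutations = enc)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' True mutations recoverable after consensus, trimming and pileup
#'
#' Restricts the injected truth set to positions that are visible in at least
#' one read window and not masked by end trimming, i.e. the set the pipeline
#' is expected to recover exactly when the artifact rate is zero. Only
#' molecules listed in `families` with at least `min_family_size` reads on
#' both strands are considered covered (others produce no double-strand
#' consensus).
#'
#' @param molecules A `true_molecules`.
#' @param config The `simulation_config` used.
#' @param families Per-molecule family sizes as returned by
#'   [simulate_reads()]; if `NULL`, every molecule is assumed covered.
#' @param min_family_size Minimum reads per strand for an SSCS.
#' @param trim List of two 1-based inclusive read-coordinate ranges masked at
#'   the consensus stage.
#' @return Data frame (pos, ref, alt), deduplicated, 0-based positions.
#' @export
truth_recoverable_mutations <- function(molecules, config, families = NULL,
                                        min_family_size = 3L,
                                        trim = list(c(1L, 8L), c(120L, 137L))) {
  RL <- config$read_length
  kept <- setdiff(seq_len(RL), unlist(lapply(trim, function(r) r[1]:r[2])))
  mols <- molecules$molecules
  ok <- rep(TRUE, nrow(mols))
  if (!is.null(families)) {
    f <- families[match(mols$id, families$id), ]
    ok <- f$n_top >= min_family_size & f$n_bottom >= min_family_size
  }
  muts <- molecules$mutations
  hit <- logical(nrow(muts))
  for (i in which(ok)) {
    s <- mols$start[i]; e <- mols$end[i]
    cov <- c(s + kept - 1L, e - kept)
    mi <- which(muts$molecule == mols$id[i])
    hit[mi] <- hit[mi] | muts$pos[mi] %in% cov
  }
  out <- unique(muts[hit, c("pos", "ref", "alt")])
  out[order(out$pos, out$alt), , drop = FALSE]
}

#' Simulate reporter-assay colony counts
#'
#' Synthetic stand-in for the transgenic reporter (gpt) fluctuation assay:
#' per animal, the chloramphenicol-resistant titer is lognormal around a
#' configured mean, and the 6-thioguanine-resistant colony count is Poisson
#' with mean titer x true mutant frequency x a gamma-distributed
#' animal-level overdispersion factor (mean 1, CV = `dispersion`).
#'
#' @param true_mf True mutant frequency in `[0, 1)`.
#' @param n_animals Number of animals.
#' @param dispersion Lognormal sdlog of the titer and CV of the
#'   overdispersion factor.
#' @param seed Integer seed.
#' @param cm_mean Mean chloramphenicol-resistant titer.
#' @param group Group label attached to every row.
#' @return Data frame (animal, group, tg_resistant, cm_resistant_mean).
#' @export
simulate_gpt_counts <- function(true_mf, n_animals, dispersion = 0.25,
                                seed = 1L, cm_mean = 2e6, group = "treated") {
  if (true_mf < 0 || true_mf >= 1) stop("true_mf must be in [0, 1)")
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  titer <- rlnorm(n_animals, log(cm_mean), dispersion)
  od <- if (dispersion > 0) {
    rgamma(n_animals, shape = 1 / dispersion^2, rate = 1 / dispersion^2)
  } else rep(1, n_animals)
  tg <- rpois(n_animals, titer * true_mf * od)
  data.frame(
    animal = sprintf("%s_%02d", group, seq_len(n_animals)), group = group,
    tg_resistant = tg, cm_resistant_mean = titer, stringsAsFactors = FALSE
  )
}
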