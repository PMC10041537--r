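#' Canonical duplex family key
#'
#' Maps a tag pair to an orientation-invariant family key: `(alpha, beta)`
#' and `(beta, alpha)` yield the same key with opposite strand labels. The
#' lexicographically smaller tag comes first; the read pair is labelled
#' `top` when its observed tag order is already canonical, `bottom`
#' otherwise. Identical tags leave the strand undefined and are flagged
#' `tie` (such families are dropped downstream). Vectorized.
#'
#' @param tag_alpha,tag_beta Tag arms (equal, non-zero length).
#' @return List with character vectors `key` and `strand`.
#' @export
canonical_family_key <- function(tag_alpha, tag_beta) {
  if (any(nchar(tag_alpha) == 0L) || any(nchar(tag_beta) == 0L)) {
    stop("tags must be non-empty")
  }
  if (any(nchar(tag_alpha) != nchar(tag_beta))) {
    stop("tag length mismatch between arms")
  }
  ordered <- tag_alpha <= tag_beta
  key <- ifelse(ordered, paste0(tag_alpha, "-", tag_beta),
                paste0(tag_beta, "-", tag_alpha))
  strand <- ifelse(tag_alpha == tag_beta, "tie",
                   ifelse(ordered, "top", "bottom"))
  list(key = key, strand = strand)
}

parse_tagged_reads <- function(fastq, mate, tag_length, spacer, read_length) {
  x <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  seqs <- as.character(x)
  tag_end <- tag_length
  sp_end <- tag_length + nchar(spacer)
  tags <- substr(seqs, 1L, tag_end)
  spac <- substr(seqs, tag_end + 1L, sp_end)
  payload <- substr(seqs, sp_end + 1L, sp_end + read_length)
  ok <- spac == spacer & !grepl("[^ACGT]", tags) &
    nchar(payload) == read_length
  data.frame(
    id = sub("\\s.*$", "", names(x)), mate = mate, tag = tags,
    payload = payload, ok = ok, stringsAsFactors = FALSE
  )
}

#' Group duplex-tagged reads into strand families
#'
#' Parses the in-sequence tag + spacer prefix of each read pair, derives the
#' canonical family key, and groups reads by (key, strand, mate). Reads with
#' a corrupted spacer, a non-ACGT tag, or a short payload are excluded and
#' counted; if more than half the reads are malformed the run aborts.
#'
#' @param fastq1,fastq2 Paired FASTQ paths.
#' @param tag_length Tag length per arm.
#' @param spacer Fixed spacer sequence between tag and payload.
#' @param read_length Payload length.
#' @return A `read_families` object: `$reads` (key, strand, mate, payload) and
#'   `$counts` (reads_in, malformed, tag_ties).
#' @export
group_families <- function(fastq1, fastq2, tag_length = 12L,
                           spacer = DUPLEX_SPACER, read_length = 137L) {
  p1 <- parse_tagged_reads(fastq1, 1L, tag_length, spacer, read_length)
  p2 <- parse_tagged_reads(fastq2, 2L, tag_length, spacer, read_length)
  if (nrow(p1) != nrow(p2) || any(sub("/[12]$", "", p1$id) !=
                                  sub("/[12]$", "", p2$id))) {
    stop("read1/read2 files are not consistently paired")
  }
  n_in <- 2L * nrow(p1)
  n_bad <- sum(!p1$ok) + sum(!p2$ok)
  if (n_in > 0 && n_bad / n_in > 0.5) {
    stop(sprintf("%d/%d reads malformed; check tag length and spacer",
                 n_bad, n_in))
  }
  # tags are attached per mate; the pair-level tag order is (tag of read1,
  # tag of read2)
  keep <- p1$ok & p2$ok
  ck <- canonical_family_key(p1$tag[keep], p2$tag[keep])
  ties <- ck$strand == "tie"
  reads <- data.frame(
    key = rep(ck$key[!ties], 2L),
    strand = rep(ck$strand[!ties], 2L),
    mate = c(rep(1L, sum(!ties)), rep(2L, sum(!ties))),
    payload = c(p1$payload[keep][!ties], p2$payload[keep][!ties]),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      reads = reads,
      counts = c(
        reads_in = n_in, malformed = n_bad,
        pairs_dropped_unparseable = sum(!keep), tag_ties = sum(ties)
      )
    ),
    class = "read_families"
  )
}

#' @export
print.read_families <- function(x, ...) {
  nf <- nrow(unique(x$reads[c("key", "strand")]))
  cat(sprintf(
    "<read_families> %d reads in, %d malformed, %d strand families\n",
    x$counts["reads_in"], x$counts["malformed"], nf
  ))
  invisible(x)
}

seq_to_codes <- function(s) utf8ToInt(s)

BASE_CODES <- utf8ToInt("ACGT")

#' Build a single-strand consensus sequence
#'
#' Per position, the base with plurality support among family members is
#' accepted when its fraction reaches `consensus_threshold`; ambiguous
#' positions (ties, or support below threshold) become N. Families smaller
#' than `min_family_size` are rejected (return `NULL`).
#'
#' @param members Character vector of equal-length member read sequences.
#' @param min_family_size Minimum reads required.
#' @param consensus_threshold Minimum supporting fraction for the plurality
#'   base.
#' @return Consensus string, or `NULL` when the family is rejected.
#' @export
build_sscs <- function(members, min_family_size = 3L,
                       consensus_threshold = 0.7) {
  if (length(members) == 0L) stop("empty family")
  if (length(members) < min_family_size) return(NULL)
  L <- nchar(members[1])
  if (any(nchar(members) != L)) {
    stop("family members of unequal length; family rejected")
  }
  m <- matrix(unlist(lapply(members, seq_to_codes), use.names = FALSE),
              nrow = length(members), byrow = TRUE)
  counts <- vapply(BASE_CODES, function(code) colSums(m == code),
                   numeric(L))        # L x 4
  if (L == 1L) counts <- matrix(counts, nrow = 1L)
  top <- max.col(counts, ties.method = "first")
  topn <- counts[cbind(seq_len(L), top)]
  tied <- rowSums(counts == topn) > 1L
  ok <- !tied & topn / length(members) >= consensus_threshold
  out <- rep("N", L)
  out[ok] <- DNA_BASES[top[ok]]
  paste(out, collapse = "")
}

#' Combine two complementary single-strand consensi into a duplex consensus
#'
#' Information is accepted only where the two strands agree perfectly: at
#' every position where both single-strand consensi carry the same non-N
#' base, that base is kept; every other position is masked to N.
#'
#' @param sscs_top,sscs_bottom Equal-length consensus strings (the bottom
#'   strand already re-oriented to top coordinates).
#' @return List with `sequence` and `n_masked`.
#' @export
build_dcs <- function(sscs_top, sscs_bottom) {
  if (nchar(sscs_top) != nchar(sscs_bottom)) {
    stop("SSCS length mismatch")
  }
  a <- strsplit(sscs_top, "")[[1]]
  b <- strsplit(sscs_bottom, "")[[1]]
  agree <- a == b & a != "N"
  out <- ifelse(agree, a, "N")
  list(sequence = paste(out, collapse = ""), n_masked = sum(!agree))
}

#' Mask-trim the ends of a duplex consensus read
#'
#' Replaces the bases in the given 1-based inclusive read-coordinate ranges
#' by N. Masking (rather than cutting) preserves read coordinates, so the
#' default ranges leave, for a 137-nt read, the informative window at
#' positions 9-119 (111 nt).
#'
#' @param sequence DCS sequence.
#' @param trim List of integer pairs, 1-based inclusive ranges (default
#'   bases 1-8 and 120-137).
#' @return The masked sequence.
#' @export
trim_dcs <- function(sequence, trim = list(c(1L, 8L), c(120L, 137L))) {
  L <- nchar(sequence)
  if (length(trim) == 0L) return(sequence)
  pos <- unlist(lapply(trim, function(r) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      stop("invalid trim range")
    }
    r[1]:r[2]
  }))
  if (any(pos > L)) stop("trim range exceeds read length")
  if (anyDuplicated(pos)) stop("overlapping trim ranges")
  s <- strsplit(sequence, "")[[1]]
  s[pos] <- "N"
  paste(s, collapse = "")
}

#' Pair complementary SSCS into DCS reads; flag and drop unpaired SSCS
#'
#' Read-1 consensi of one strand family are paired with the read-2 consensi
#' of the complementary family (both cover the same fragment end in the same
#' as-sequenced orientation). SSCS without a complementary partner are
#' counted and ignored.
#'
#' @param sscs Data frame with columns `key`, `strand`, `mate`, `sequence`.
#' @return List with `dcs` (key, end, sequence, n_masked) and `n_unpaired`.
#' @export
pair_and_filter <- function(sscs) {
  by_key <- split(seq_len(nrow(sscs)), sscs$key)
  dcs_key <- character(0); dcs_end <- character(0)
  dcs_seq <- character(0); dcs_nm <- integer(0)
  n_unpaired <- 0L
  for (k in names(by_key)) {
    sub <- sscs[by_key[[k]], , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    # fragment end "F": (top, mate1) + (bottom, mate2)
    # fragment end "R": (top, mate2) + (bottom, mate1)
    for (endlab in c("F", "R")) {
      m_top <- if (endlab == "F") 1L else 2L
      i <- which(sub$strand == "top" & sub$mate == m_top)
      j <- which(sub$strand == "bottom" & sub$mate == 3L - m_top)
      if (length(i) == 1L && length(j) == 1L) {
        d <- build_dcs(sub$sequence[i], sub$sequence[j])
        dcs_key <- c(dcs_key, k); dcs_end <- c(dcs_end, endlab)
        dcs_seq <- c(dcs_seq, d$sequence); dcs_nm <- c(dcs_nm, d$n_masked)
        used[c(i, j)] <- TRUE
      }
    }
    n_unpaired <- n_unpaired + sum(!used)
  }
  list(
    dcs = data.frame(key = dcs_key, end = dcs_end, sequence = dcs_seq,
                     n_masked = dcs_nm, stringsAsFactors = FALSE),
    n_unpaired = n_unpaired
  )
}

#' Full duplex consensus pipeline stage
#'
#' Groups tagged reads into strand families, builds single-strand consensus
#' sequences, pairs complementary families into double-strand consensus
#' reads, optionally rejects reads with any strand disagreement, and
#' mask-trims the read ends.
#'
#' @param fastq1,fastq2 Paired tagged FASTQ paths.
#' @param min_family_size Minimum reads per strand family (default 3).
#' @param consensus_threshold Plurality fraction required per SSCS base
#'   (default 0.7).
#' @param trim List of 1-based inclusive trim ranges (default bases 1-8 and
#'   120-137); `list()` disables trimming.
#' @param reject_on_disagreement Drop a DCS entirely if any position
#'   disagrees between strands, instead of masking that position.
#' @param tag_length,spacer,read_length Tag scheme (must match the library).
#' @return A `duplex_consensus` object: `$dcs` data frame (key, end,
#'   sequence, n_masked) and `$report` named counter vector.
#' @export
duplex_consensus <- function(fastq1, fastq2, min_family_size = 3L,
                             consensus_threshold = 0.7,
                             trim = list(c(1L, 8L), c(120L, 137L)),
                             reject_on_disagreement = FALSE,
                             tag_length = 12L, spacer = DUPLEX_SPACER,
                             read_length = 137L) {
  fam <- group_families(fastq1, fastq2, tag_length, spacer, read_length)
  reads <- fam$reads
  grp <- interaction(reads$key, reads$strand, reads$mate, drop = TRUE)
  groups <- split(reads$payload, grp)
  # split() orders by factor level; take each group's metadata from its
  # first member in that same order
  first_idx <- match(levels(grp), as.character(grp))
  meta <- reads[first_idx, c("key", "strand", "mate")]

  n_rejected_size <- 0L
  cons <- character(length(groups))
  keep <- logical(length(groups))
  for (i in seq_along(groups)) {
    s <- build_sscs(groups[[i]], min_family_size, consensus_threshold)
    if (is.null(s)) {
      n_rejected_size <- n_rejected_size + 1L
    } else {
      cons[i] <- s
      keep[i] <- TRUE
    }
  }
  sscs <- data.frame(
    key = meta$key[keep], strand = meta$strand[keep], mate = meta$mate[keep],
    sequence = cons[keep], stringsAsFactors = FALSE
  )
  paired <- pair_and_filter(sscs)
  dcs <- paired$dcs
  if (reject_on_disagreement && nrow(dcs)) {
    dcs <- dcs[dcs$n_masked == 0L, , drop = FALSE]
  }
  if (nrow(dcs)) {
    dcs$sequence <- vapply(dcs$sequence, trim_dcs, character(1), trim = trim,
                           USE.NAMES = FALSE)
  }
  masked_frac <- if (nrow(dcs)) {
    tot <- sum(nchar(dcs$sequence))
    sum(vapply(dcs$sequence,
               function(s) sum(strsplit(s, "")[[1]] == "N"), numeric(1))) / tot
  } else NA_real_
  structure(
    list(
      dcs = dcs,
      report = c(
        fam$counts,
        strand_families = length(groups),
        sscs_built = nrow(sscs),
        sscs_rejected_size = n_rejected_size,
        sscs_unpaired = paired$n_unpaired,
        dcs_built = nrow(dcs),
        masked_base_fraction = masked_frac
      )
    ),
    class = "duplex_consensus"
  )
}

#' @export
print.duplex_consensus <- function(x, ...) {
  cat("<duplex_consensus>\n")
  for (nm in names(x$report)) {
    cat(sprintf("  %-28s %s\n", nm, format(x$report[[nm]])))
  }
  invisible(x)
}

#' Write DCS reads as FASTQ (constant qualities)
#'
#' @param consensus A `duplex_consensus`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_dcs_fastq <- function(consensus, path) {
  d <- consensus$dcs
  write_fastq(d$sequence, paste0(d$key, "/", d$end), path)
}
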