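#' Build an exact k-mer index of reference regions
#'
#' @param regions List of `reference_region` objects.
#' @param k Seed length.
#' @return A `kmer_index` (hashed environment of k-mer -> positions).
#' @keywords internal
build_kmer_index <- function(regions, k = 20L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (r in regions) {
    n <- r$length - k + 1L
    km <- substring(r$sequence, seq_len(n), seq_len(n) + k - 1L)
    for (i in seq_len(n)) {
      key <- km[i]
      hit <- env[[key]]
      entry <- c(r$name, i - 1L)   # 0-based start
      env[[key]] <- if (is.null(hit)) list(entry) else c(hit, list(entry))
    }
  }
  structure(list(env = env, k = k, regions = regions), class = "kmer_index")
}

nonN_runs <- function(chars) {
  r <- rle(chars != "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

place_one_orientation <- function(chars, index, region_map, min_identity,
                                  max_seeds = 8L) {
  k <- index$k
  runs <- nonN_runs(chars)
  runs <- runs[runs$len >= k, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  runs <- runs[order(-runs$len), , drop = FALSE]
  seq_str <- paste(chars, collapse = "")
  tried <- character(0)
  best <- NULL
  n_seed <- 0L
  for (ri in seq_len(nrow(runs))) {
    # tile the run with non-overlapping k-mers so a substitution inside one
    # seed cannot defeat placement
    offsets <- unique(pmin(
      seq(runs$start[ri], runs$end[ri] - k + 1L, by = k),
      runs$end[ri] - k + 1L
    ))
    for (off in offsets) {
      if (n_seed >= max_seeds) break
      n_seed <- n_seed + 1L
      seed <- substr(seq_str, off, off + k - 1L)
      hits <- index$env[[seed]]
      if (is.null(hits)) next
      for (h in hits) {
        rname <- h[[1]]; spos <- as.integer(h[[2]])
        start <- spos - (off - 1L)     # implied 0-based read start
        reg <- region_map[[rname]]
        if (start < 0L || start + length(chars) > reg$length) next
        key <- paste(rname, start)
        if (key %in% tried) next
        tried <- c(tried, key)
        refw <- substr(reg$sequence, start + 1L, start + length(chars))
        refc <- strsplit(refw, "")[[1]]
        informative <- chars != "N"
        if (!any(informative)) next
        ident <- sum(chars[informative] == refc[informative]) /
          sum(informative)
        if (is.null(best) || ident > best$identity) {
          best <- list(region = rname, start = start, identity = ident)
        }
      }
    }
  }
  if (!is.null(best) && best$identity >= min_identity) best else NULL
}

#' Place a DCS read on the reference by exact-seed ungapped alignment
#'
#' Exact-match seeding on non-N k-mers in both orientations, followed by
#' ungapped extension over the full read; the best placement by identity is
#' kept, and reads below `min_identity` (or with no seed hit) are reported
#' unmapped. This simple placer is exact for substitution-only duplex
#' consensus reads; externally produced alignments can be supplied to
#' [pileup()] instead for real gapped data.
#'
#' @param sequence DCS sequence (may contain N).
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param min_identity Minimum identity over non-N positions (default 0.9).
#' @return List (region, start, strand, identity) or `NULL` if unmapped.
#' @export
align_dcs <- function(sequence, index, min_identity = 0.9) {
  region_map <- setNames(index$regions,
                         vapply(index$regions, `[[`, "", "name"))
  chars <- strsplit(sequence, "")[[1]]
  fwd <- place_one_orientation(chars, index, region_map, min_identity)
  rchars <- strsplit(revcomp(sequence), "")[[1]]
  rev <- place_one_orientation(rchars, index, region_map, min_identity)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (is.null(rev) || (!is.null(fwd) && fwd$identity >= rev$identity)) {
    c(fwd, strand = "+")
  } else {
    c(rev, strand = "-")
  }
}

#' Place a set of DCS reads
#'
#' @param consensus A `duplex_consensus` (or data frame with `sequence`).
#' @param regions List of `reference_region`.
#' @param seed_length Seed k-mer length (default 20).
#' @param min_identity Minimum placement identity (default 0.9).
#' @return A `dcs_placements` object: `$placements` data frame (id, region,
#'   start, strand, identity, sequence in + orientation) and `$n_unmapped`.
#' @export
align_dcs_set <- function(consensus, regions, seed_length = 20L,
                          min_identity = 0.9) {
  d <- if (inherits(consensus, "duplex_consensus")) consensus$dcs else consensus
  index <- build_kmer_index(regions, seed_length)
  ids <- if (!is.null(d$key)) paste0(d$key, "/", d$end) else
    as.character(seq_len(nrow(d)))
  out <- vector("list", nrow(d))
  n_unmapped <- 0L
  for (i in seq_len(nrow(d))) {
    p <- align_dcs(d$sequence[i], index, min_identity)
    if (is.null(p)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    seq_plus <- if (p$strand == "+") d$sequence[i] else revcomp(d$sequence[i])
    out[[i]] <- data.frame(
      id = ids[i], region = p$region, start = p$start, strand = p$strand,
      identity = p$identity, sequence = seq_plus, stringsAsFactors = FALSE
    )
  }
  placements <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(placements)) {
    placements <- data.frame(
      id = character(0), region = character(0), start = integer(0),
      strand = character(0), identity = numeric(0), sequence = character(0)
    )
  }
  structure(list(placements = placements, n_unmapped = n_unmapped),
            class = "dcs_placements")
}

#' @export
print.dcs_placements <- function(x, ...) {
  cat(sprintf("<dcs_placements> %d placed, %d unmapped\n",
              nrow(x$placements), x$n_unmapped))
  invisible(x)
}

#' Pile placed reads onto the reference
#'
#' Accumulates per-position base counts from placed DCS reads; N bases
#' contribute nothing. Columns with zero depth are omitted.
#'
#' @param placements A `dcs_placements` (or its `$placements` data frame with
#'   reads already oriented to the + strand).
#' @param regions List of `reference_region`.
#' @return A `pileup` object: data frame (region, pos (0-based), ref, depth,
#'   A, C, G, T).
#' @export
pileup <- function(placements, regions) {
  p <- if (inherits(placements, "dcs_placements")) placements$placements else
    placements
  region_map <- setNames(regions, vapply(regions, `[[`, "", "name"))
  out <- list()
  for (rname in unique(p$region)) {
    reg <- region_map[[rname]]
    if (is.null(reg)) stop("placement on unknown region '", rname, "'")
    sub <- p[p$region == rname, , drop = FALSE]
    L <- reg$length
    pos_all <- integer(0); base_all <- integer(0)
    npos <- sum(nchar(sub$sequence))
    pos_all <- integer(npos); base_all <- integer(npos); at <- 0L
    for (i in seq_len(nrow(sub))) {
      codes <- seq_to_codes(sub$sequence[i])
      len <- length(codes)
      if (sub$start[i] < 0L || sub$start[i] + len > L) {
        stop("placement outside region bounds")
      }
      idx <- at + seq_len(len)
      pos_all[idx] <- sub$start[i] + seq_len(len) - 1L   # 0-based
      base_all[idx] <- match(codes, BASE_CODES)          # NA for N
      at <- at + len
    }
    ok <- !is.na(base_all)
    pos_all <- pos_all[ok]; base_all <- base_all[ok]
    if (!length(pos_all)) next
    tab <- tabulate(pos_all * 4L + base_all, nbins = 4L * (L - 1L) + 4L)
    counts <- matrix(tab, ncol = 4L, byrow = TRUE)   # row p+1 = position p
    depth <- rowSums(counts)
    covered <- which(depth > 0)
    refc <- strsplit(reg$sequence, "")[[1]]
    out[[rname]] <- data.frame(
      region = rname, pos = covered - 1L, ref = refc[covered],
      depth = depth[covered],
      A = counts[covered, 1], C = counts[covered, 2],
      G = counts[covered, 3], T = counts[covered, 4],
      stringsAsFactors = FALSE
    )
  }
  columns <- if (length(out)) do.call(rbind, out) else
    data.frame(region = character(0), pos = integer(0), ref = character(0),
               depth = integer(0), A = integer(0), C = integer(0),
               G = integer(0), T = integer(0))
  rownames(columns) <- NULL
  structure(columns, class = c("pileup", "data.frame"))
}

#' Call substitutions from a pileup
#'
#' One call per (position, alternate base) with non-zero support. The
#' trinucleotide context is taken from the reference; calls at region ends
#' keep `NA` context and are excluded from spectra later.
#'
#' @param columns A `pileup`.
#' @param regions List of `reference_region`.
#' @return Data frame (region, pos (0-based), ref, alt, observations,
#'   context3).
#' @export
call_mutations <- function(columns, regions) {
  region_map <- setNames(regions, vapply(regions, `[[`, "", "name"))
  res <- list()
  for (b in DNA_BASES) {
    cnt <- columns[[b]]
    hit <- which(cnt > 0 & columns$ref != b)
    if (!length(hit)) next
    res[[b]] <- data.frame(
      region = columns$region[hit], pos = columns$pos[hit],
      ref = columns$ref[hit], alt = b, observations = cnt[hit],
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(res)) do.call(rbind, res) else
    data.frame(region = character(0), pos = integer(0), ref = character(0),
               alt = character(0), observations = integer(0))
  rownames(calls) <- NULL
  calls <- calls[order(calls$region, calls$pos, calls$alt), , drop = FALSE]
  ctx <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    reg <- region_map[[calls$region[i]]]
    p <- calls$pos[i]
    if (p >= 1L && p <= reg$length - 2L) {
      ctx[i] <- substr(reg$sequence, p, p + 2L)
    }
  }
  calls$context3 <- ctx
  rownames(calls) <- NULL
  calls
}

#' Collapse calls to unique mutations
#'
#' A mutation at a given genomic location is counted only once, regardless of
#' how many independent DCS reads observed it. The default deduplication key
#' is (region, position, alt), which keeps distinct alternate alleles at one
#' site as distinct mutations; `dedup_by = "position"` keeps only the
#' first-sorted alternate per site (the stricter reading).
#'
#' @param calls Data frame from [call_mutations()].
#' @param dedup_by `"position_alt"` (default) or `"position"`.
#' @return The deduplicated calls with `observations` collapsed to 1.
#' @export
unique_mutations <- function(calls, dedup_by = c("position_alt", "position")) {
  dedup_by <- match.arg(dedup_by)
  key <- if (dedup_by == "position_alt") {
    paste(calls$region, calls$pos, calls$alt)
  } else {
    paste(calls$region, calls$pos)
  }
  out <- calls[!duplicated(key), , drop = FALSE]
  out$observations <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a mutation list as TSV (1-based positions)
#'
#' @param mutations Mutation data frame (0-based `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_tsv <- function(mutations, path) {
  out <- mutations
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a mutation list as a minimal substitution-only VCF
#'
#' @param mutations Mutation data frame (0-based `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(mutations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=duplexspectra",
    "##INFO=<ID=OBS,Number=1,Type=Integer,Description=\"DCS observations\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(mutations)) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tOBS=%d",
      mutations$region, mutations$pos + 1L, mutations$ref, mutations$alt,
      mutations$observations
    ), con)
  }
  invisible(path)
}
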