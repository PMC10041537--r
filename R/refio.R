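#' @importFrom stats rbinom rpois rlnorm rgamma runif pbinom dbinom setNames
#' @importFrom utils combn read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Load reference target regions from a FASTA file
#'
#' Reads a (multi-record) FASTA file and returns one reference region per
#' record. Sequences are uppercased and must contain only A/C/G/T: ambiguity
#' codes in a curated target region indicate a data problem and are rejected
#' rather than silently skipped.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A list of `reference_region` objects, each with elements `name`,
#'   `sequence` and `length`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t", "ACGTACGT"), fa)
#' load_reference(fa)[[1]]$length
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("reference FASTA is empty: ", path)
  regions <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    nm <- sub("\\s.*$", "", names(seqs)[i])
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0L) {
      stop(sprintf(
        "record '%s': non-ACGT character '%s' at offset %d",
        nm, substr(s, bad, bad), as.integer(bad)
      ))
    }
    regions[[i]] <- reference_region(nm, s)
  }
  regions
}

#' Construct a reference region
#'
#' @param name Region identifier.
#' @param sequence Uppercase DNA string over A/C/G/T.
#' @return A `reference_region` object.
#' @export
reference_region <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("region '", name, "' contains non-ACGT characters")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "reference_region"
  )
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf(
    "<reference_region> %s: %d nt (%s...)\n",
    x$name, x$length, substr(x$sequence, 1, 20)
  ))
  invisible(x)
}

all_trinucleotides <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

pyrimidine_trinucleotides <- function() {
  tri <- all_trinucleotides()
  tri[substr(tri, 2, 2) %in% c("C", "T")]
}

#' Trinucleotide composition of a reference region
#'
#' Counts every interior trinucleotide (positions 1..length-2, 0-based; no
#' wraparound or padding) and reports absolute counts, relative frequencies,
#' and strand-collapsed frequencies over the 32 pyrimidine-centered
#' trinucleotides. The collapsed frequencies are the normalization baseline
#' for 96-channel spectra: each spectrum channel's frequency is divided by
#' how often its trinucleotide context occurs in the sequenced target.
#'
#' @param region A `reference_region` (or a list of them, pooled).
#' @return A `trinuc_composition` object with `counts` (64), `relative` (64,
#'   sums to 1) and `collapsed` (32 pyrimidine-centered, sums to 1).
#' @export
trinucleotide_composition <- function(region) {
  regions <- if (inherits(region, "reference_region")) list(region) else region
  counts <- setNames(integer(64), all_trinucleotides())
  for (r in regions) {
    if (r$length < 3L) stop("region '", r$name, "' is shorter than 3 nt")
    tri <- substring(r$sequence, seq_len(r$length - 2L), 3:r$length)
    tab <- table(tri)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  relative <- counts / sum(counts)
  pyr <- pyrimidine_trinucleotides()
  collapsed <- setNames(relative[pyr] + relative[revcomp(pyr)], pyr)
  structure(
    list(counts = counts, relative = relative, collapsed = collapsed),
    class = "trinuc_composition"
  )
}

#' @export
print.trinuc_composition <- function(x, ...) {
  cat(sprintf(
    "<trinuc_composition> %d trinucleotides counted, %d distinct\n",
    sum(x$counts), sum(x$counts > 0)
  ))
  invisible(x)
}

#' Write a trinucleotide composition as TSV
#'
#' @param comp A `trinuc_composition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(comp, path) {
  df <- data.frame(
    trinucleotide = names(comp$counts),
    count = as.integer(comp$counts),
    relative_frequency = as.numeric(comp$relative)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the sequence context around a position
#'
#' Returns the window of `2 * flank + 1` reference bases centered on `pos`.
#' The spectrum code uses `flank = 1` (trinucleotides); the probability-logo
#' code uses `flank = 7` (15-base windows). Windows that would run off either
#' end of the region are an error; callers that scan many positions skip and
#' count them instead.
#'
#' @param region A `reference_region`.
#' @param pos 0-based position of the center base.
#' @param flank Number of bases on each side (>= 1).
#' @return A DNA string of length `2 * flank + 1`.
#' @export
extract_context <- function(region, pos, flank = 1L) {
  if (flank < 1L) stop("flank must be >= 1")
  if (pos - flank < 0L || pos + flank >= region$length) {
    stop(sprintf(
      "context window [%d, %d] out of range for region '%s' (length %d)",
      pos - flank, pos + flank, region$name, region$length
    ))
  }
  substr(region$sequence, pos - flank + 1L, pos + flank + 1L)
}

#' Reverse complement
#'
#' Vectorized reverse complement over A/C/G/T/N strings.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) stop("revcomp: invalid character in sequence")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}
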