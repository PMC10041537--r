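SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The canonical 96-channel ordering
#'
#' Channels follow the pyrimidine-centered convention used for single-base
#' substitution signatures: six substitution types (C>A, C>G, C>T, T>A, T>C,
#' T>G), each in 16 flanking-base contexts, written e.g. `A[C>T]G`. Contexts
#' are ordered by 5' base then 3' base (A, C, G, T).
#'
#' @return Character vector of the 96 channel labels in canonical order.
#' @export
spectrum_channels <- function() {
  out <- character(0)
  for (sub in SUBSTITUTION_TYPES) {
    ref <- substr(sub, 1, 1)
    for (b5 in DNA_BASES) {
      for (b3 in DNA_BASES) {
        out <- c(out, paste0(b5, "[", sub, "]", b3))
      }
    }
  }
  out
}

channel_trinuc <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}

channel_alt <- function(channel) substr(channel, 5, 5)

#' Map a substitution to its pyrimidine-centered channel
#'
#' Purine-centered substitutions (ref G or A) are mapped onto the equivalent
#' pyrimidine-centered channel by reverse-complementing the context and
#' complementing both alleles, so the 192 raw (ref, alt, context) combinations
#' collapse two-to-one onto 96 channels. Vectorized.
#'
#' @param ref Reference base(s) at the mutated position.
#' @param alt Alternate base(s); must differ from `ref`.
#' @param context3 Reference trinucleotide(s) whose center equals `ref`.
#' @return Channel label(s), e.g. `"A[C>T]G"`.
#' @examples
#' channel_of("C", "T", "ACG")  # "A[C>T]G"
#' channel_of("G", "A", "GGC")  # "G[C>T]C"
#' @export
channel_of <- function(ref, alt, context3) {
  n <- max(length(ref), length(alt), length(context3))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context3 <- rep_len(toupper(context3), n)
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)) {
    stop("channel_of: ref and alt must be single bases in ACGT")
  }
  if (any(ref == alt)) stop("channel_of: alt must differ from ref")
  if (any(substr(context3, 2, 2) != ref)) {
    stop("channel_of: context3 center must equal ref")
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    context3[pur] <- revcomp(context3[pur])
    ref[pur] <- complement_base(ref[pur])
    alt[pur] <- complement_base(alt[pur])
  }
  paste0(
    substr(context3, 1, 1), "[", ref, ">", alt, "]", substr(context3, 3, 3)
  )
}

#' Construct a 96-channel spectrum object
#'
#' @param counts Named numeric vector over channels (missing channels are 0).
#' @param frequency Optional named frequency vector (sums to 1).
#' @param meta Optional list of metadata (sample name, group, provenance).
#' @return A `spectrum96` object.
#' @export
spectrum96 <- function(counts = NULL, frequency = NULL, meta = list()) {
  ch <- spectrum_channels()
  cts <- setNames(numeric(96), ch)
  if (!is.null(counts)) {
    if (is.null(names(counts))) {
      if (length(counts) != 96) stop("unnamed counts must have length 96")
      cts[] <- counts
    } else {
      unknown <- setdiff(names(counts), ch)
      if (length(unknown)) stop("unknown channel label(s): ",
                                paste(head(unknown, 3), collapse = ", "))
      cts[names(counts)] <- counts
    }
  }
  if (any(cts < 0)) stop("channel counts must be non-negative")
  freq <- NULL
  if (!is.null(frequency)) {
    f <- setNames(numeric(96), ch)
    if (is.null(names(frequency))) {
      if (length(frequency) != 96) stop("unnamed frequency must have length 96")
      f[] <- frequency
    } else {
      f[names(frequency)] <- frequency
    }
    if (any(f < 0)) stop("channel frequencies must be non-negative")
    tot <- sum(f)
    if (tot <= 0) stop("frequency vector is all zero")
    if (abs(tot - 1) > 1e-9) f <- f / tot
    freq <- f
  }
  structure(
    list(channels = ch, counts = cts, frequency = freq, meta = meta),
    class = "spectrum96"
  )
}

#' @export
print.spectrum96 <- function(x, ...) {
  nm <- if (!is.null(x$meta$sample)) x$meta$sample else "unnamed"
  cat(sprintf("<spectrum96> %s: %g mutations", nm, sum(x$counts)))
  if (!is.null(x$frequency)) {
    top <- sort(x$frequency, decreasing = TRUE)[1:3]
    cat(sprintf("; top channels %s",
                paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
  }
  cat("\n")
  invisible(x)
}

#' @method as.data.frame spectrum96
#' @export
as.data.frame.spectrum96 <- function(x, ...) {
  data.frame(
    channel = x$channels,
    count = as.numeric(x$counts),
    frequency = if (is.null(x$frequency)) NA_real_ else as.numeric(x$frequency)
  )
}

spectrum_freq <- function(s) {
  if (inherits(s, "spectrum96")) {
    if (!is.null(s$frequency)) return(as.numeric(s$frequency))
    tot <- sum(s$counts)
    if (tot == 0) stop("spectrum has zero total count and no frequencies")
    return(as.numeric(s$counts) / tot)
  }
  as.numeric(s)
}

#' Build a counts spectrum from unique mutation calls
#'
#' Each unique mutation increments its pyrimidine-centered channel once.
#' Mutations without a usable trinucleotide context (calls at region ends)
#' are excluded and counted in `meta$n_excluded`.
#'
#' @param mutations Data frame with columns `ref`, `alt`, `context3` (as
#'   produced by [unique_mutations()]).
#' @param meta Optional metadata list.
#' @return A `spectrum96` with counts filled in.
#' @export
build_spectrum <- function(mutations, meta = list()) {
  ok <- !is.na(mutations$context3) & nchar(mutations$context3) == 3L
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    warning(n_excl, " mutation(s) without trinucleotide context excluded")
  }
  m <- mutations[ok, , drop = FALSE]
  cts <- setNames(numeric(96), spectrum_channels())
  if (nrow(m) > 0) {
    ch <- channel_of(m$ref, m$alt, m$context3)
    tab <- table(ch)
    cts[names(tab)] <- as.numeric(tab)
  }
  meta$n_excluded <- n_excl
  spectrum96(counts = cts, meta = meta)
}

#' Normalize a spectrum by target trinucleotide composition
#'
#' Divides each channel's count proportion by the strand-collapsed relative
#' frequency of its trinucleotide context in the sequenced target, then
#' rescales so the result sums to 1. Channels whose context does not occur in
#' the target get frequency 0 and are recorded in `meta$absent_channels`.
#'
#' @param s A `spectrum96` with counts.
#' @param comp A `trinuc_composition` of the region(s) the mutations came from.
#' @return A `spectrum96` carrying normalized frequencies.
#' @export
normalize_spectrum <- function(s, comp) {
  tot <- sum(s$counts)
  if (tot == 0) stop("cannot normalize an all-zero spectrum")
  tri <- channel_trinuc(s$channels)
  w <- as.numeric(comp$collapsed[tri])
  f <- as.numeric(s$counts) / tot
  absent <- w <= 0
  f[absent] <- 0
  f[!absent] <- f[!absent] / w[!absent]
  f <- f / sum(f)
  meta <- s$meta
  meta$absent_channels <- s$channels[absent & s$counts > 0]
  spectrum96(counts = s$counts, frequency = setNames(f, s$channels), meta = meta)
}

#' Subtract a background spectrum
#'
#' Per-channel clamped subtraction on normalized frequencies
#' (`max(0, s - scale * bg)`), then rescaling to sum 1. This is the baseline
#' correction applied to treated-sample spectra before signature comparison:
#' the vehicle-control spectrum is subtracted and the remainder renormalized.
#'
#' @param s Sample `spectrum96` (normalized).
#' @param bg Background `spectrum96` (normalized on the same composition).
#' @param scale Multiplier applied to the background before subtraction.
#' @return A background-corrected `spectrum96`.
#' @export
subtract_background <- function(s, bg, scale = 1) {
  fs <- spectrum_freq(s)
  fb <- spectrum_freq(bg)
  d <- pmax(0, fs - scale * fb)
  if (sum(d) <= 0) {
    stop("background subtraction left an all-zero spectrum")
  }
  d <- d / sum(d)
  meta <- if (inherits(s, "spectrum96")) s$meta else list()
  meta$background_subtracted <- TRUE
  spectrum96(
    counts = if (inherits(s, "spectrum96")) s$counts else NULL,
    frequency = setNames(d, spectrum_channels()), meta = meta
  )
}

#' Cosine similarity between two spectra
#'
#' @param a,b `spectrum96` objects or numeric 96-vectors.
#' @return Cosine similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  va <- spectrum_freq(a)
  vb <- spectrum_freq(b)
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(va * vb) / (na * nb)
}

#' Cosine-similarity matrix of spectra and signatures
#'
#' Sample spectra are background-corrected (when `background` is supplied)
#' before comparison; signature vectors are compared as given. The result is
#' symmetric with unit diagonal.
#'
#' @param spectra Named list of sample `spectrum96` objects.
#' @param signatures Optional named list of signature `spectrum96` objects.
#' @param background Optional `spectrum96` subtracted from every sample
#'   spectrum first.
#' @return A `cosine_matrix` object wrapping the labelled similarity matrix.
#' @export
similarity_matrix <- function(spectra, signatures = NULL, background = NULL) {
  if (!is.null(background)) {
    spectra <- lapply(spectra, subtract_background, bg = background)
  }
  all <- c(spectra, signatures)
  if (length(all) < 2) stop("need at least two spectra/signatures")
  labs <- names(all)
  if (is.null(labs) || any(!nzchar(labs))) {
    labs <- paste0("S", seq_along(all))
  }
  n <- length(all)
  m <- matrix(1, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- cosine_similarity(all[[i]], all[[j]])
      if (j < i) m[i, j] <- m[j, i]
    }
  }
  structure(list(labels = labs, values = m), class = "cosine_matrix")
}

#' @export
print.cosine_matrix <- function(x, digits = 3, ...) {
  cat("<cosine_matrix>\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Heatmap of a cosine-similarity matrix
#'
#' @param x A `cosine_matrix`.
#' @param ... Passed to [graphics::image()].
#' @method plot cosine_matrix
#' @export
plot.cosine_matrix <- function(x, ...) {
  n <- nrow(x$values)
  graphics::image(
    seq_len(n), seq_len(n), t(x$values[n:1, , drop = FALSE]),
    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...
  )
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Average spectra across animals
#'
#' Per-animal spectra are normalized individually and their frequency vectors
#' averaged (the default for reporting group spectra); set `pool_counts = TRUE`
#' to sum raw counts first instead.
#'
#' @param spectra List of `spectrum96` objects.
#' @param comp `trinuc_composition` used to normalize.
#' @param pool_counts Pool counts before normalizing instead of averaging
#'   normalized frequencies.
#' @return A `spectrum96` with group frequencies (counts are the pooled sum).
#' @export
average_spectra <- function(spectra, comp, pool_counts = FALSE) {
  cts <- Reduce(`+`, lapply(spectra, function(s) as.numeric(s$counts)))
  pooled <- spectrum96(setNames(cts, spectrum_channels()))
  if (pool_counts) return(normalize_spectrum(pooled, comp))
  fmat <- vapply(
    spectra,
    function(s) spectrum_freq(normalize_spectrum(s, comp)),
    numeric(96)
  )
  f <- rowMeans(fmat)
  spectrum96(
    counts = pooled$counts,
    frequency = setNames(f / sum(f), spectrum_channels()),
    meta = list(n_samples = length(spectra))
  )
}

#' Read a 96-row signature/spectrum TSV
#'
#' Expects columns `channel` and `frequency` (a `count` column is carried
#' along when present). Channels are validated against the canonical set and
#' reordered canonically; frequencies are renormalized on load with a warning
#' if they deviate from 1 by more than 1e-6.
#'
#' @param path TSV path.
#' @return A `spectrum96`.
#' @export
read_signature <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "frequency") %in% names(df))) {
    stop("signature file must have columns 'channel' and 'frequency'")
  }
  if (nrow(df) != 96) stop("signature file must have exactly 96 rows, got ",
                           nrow(df))
  ch <- spectrum_channels()
  if (!setequal(df$channel, ch)) {
    stop("signature file channel labels do not match the canonical 96-set")
  }
  if (any(df$frequency < 0)) stop("negative frequency in signature file")
  df <- df[match(ch, df$channel), ]
  tot <- sum(df$frequency)
  if (tot <= 0) stop("signature frequencies sum to zero")
  if (abs(tot - 1) > 1e-6) {
    warning(sprintf("signature frequencies sum to %.8f; renormalizing", tot))
  }
  cts <- if ("count" %in% names(df)) setNames(df$count, ch) else NULL
  spectrum96(
    counts = cts,
    frequency = setNames(df$frequency / tot, ch),
    meta = list(source = path)
  )
}

#' Write a spectrum as TSV
#'
#' Columns: channel, count, frequency.
#'
#' @param s A `spectrum96`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  df <- as.data.frame(s)
  if (all(is.na(df$frequency))) {
    tot <- sum(df$count)
    df$frequency <- if (tot > 0) df$count / tot else 0
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bar plot of a 96-channel spectrum
#'
#' Pyrimidine-centered channels by default; `purine_centered = TRUE` relabels
#' channels on the purine strand (e.g. `C[G>A]C` for `G[C>T]G`), the display
#' convention used for reporter-region plots of GC->AT-dominated spectra.
#'
#' @param x A `spectrum96`.
#' @param purine_centered Relabel channels purine-centered.
#' @param ... Passed to [graphics::barplot()].
#' @method plot spectrum96
#' @export
plot.spectrum96 <- function(x, purine_centered = FALSE, ...) {
  f <- spectrum_freq(x)
  labs <- x$channels
  if (purine_centered) {
    tri <- revcomp(channel_trinuc(labs))
    ref <- complement_base(substr(labs, 3, 3))
    alt <- complement_base(channel_alt(labs))
    labs <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                   substr(tri, 3, 3))
  }
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  graphics::barplot(f, names.arg = labs, col = cols, border = NA, las = 2,
                    cex.names = 0.35, ylab = "frequency", ...)
  invisible(x)
}
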