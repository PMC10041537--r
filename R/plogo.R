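#' Extract foreground context windows around mutated bases
#'
#' For each unique mutation matching the requested substitution on either
#' strand, extracts the `2 * flank + 1` reference window and orients it so
#' the center reads `ref_base` (reverse-complementing windows where the
#' mutation is represented on the opposite strand). Mutations closer than
#' `flank` to a region end are skipped and counted.
#'
#' @param mutations Unique-mutation data frame (region, pos (0-based), ref,
#'   alt).
#' @param regions List of `reference_region`.
#' @param ref_base,alt_base The substitution analyzed (default G->A).
#' @param flank Window half-width (default 7, i.e. 15-base windows).
#' @return A `context_windows` object: `$windows`, `$n`, `$n_skipped`,
#'   `$role = "foreground"`, `$center`.
#' @export
extract_foreground_windows <- function(mutations, regions, ref_base = "G",
                                       alt_base = "A", flank = 7L) {
  region_map <- setNames(regions, vapply(regions, `[[`, "", "name"))
  comp_ref <- complement_base(ref_base)
  comp_alt <- complement_base(alt_base)
  fwd <- mutations$ref == ref_base & mutations$alt == alt_base
  rev <- mutations$ref == comp_ref & mutations$alt == comp_alt
  sel <- which(fwd | rev)
  windows <- character(0)
  n_skipped <- 0L
  for (i in sel) {
    reg <- region_map[[mutations$region[i]]]
    p <- mutations$pos[i]
    if (p - flank < 0L || p + flank >= reg$length) {
      n_skipped <- n_skipped + 1L
      next
    }
    w <- extract_context(reg, p, flank)
    if (rev[i]) w <- revcomp(w)
    windows <- c(windows, w)
  }
  structure(
    list(windows = windows, n = length(windows), n_skipped = n_skipped,
         role = "foreground", center = ref_base, flank = flank),
    class = "context_windows"
  )
}

#' Extract background context windows from the sequenced target
#'
#' All windows centered on occurrences of `ref_base` on either strand of the
#' given regions (occurrences on the opposite strand contribute the
#' reverse-complemented window), optionally subsampled with a seed.
#'
#' @param regions List of `reference_region`.
#' @param ref_base Center base (default G).
#' @param flank Window half-width (default 7).
#' @param sample_size Optional uniform subsample size.
#' @param seed Seed used when subsampling.
#' @return A `context_windows` object with `role = "background"`.
#' @export
extract_background_windows <- function(regions, ref_base = "G", flank = 7L,
                                       sample_size = NULL, seed = 1L) {
  if (inherits(regions, "reference_region")) regions <- list(regions)
  comp <- complement_base(ref_base)
  windows <- list()
  for (reg in regions) {
    chars <- strsplit(reg$sequence, "")[[1]]
    pos <- which(chars %in% c(ref_base, comp)) - 1L   # 0-based
    pos <- pos[pos - flank >= 0L & pos + flank < reg$length]
    if (!length(pos)) next
    w <- substring(reg$sequence, pos - flank + 1L, pos + flank + 1L)
    flip <- chars[pos + 1L] == comp
    if (any(flip)) w[flip] <- revcomp(w[flip])
    windows[[reg$name]] <- w
  }
  windows <- unlist(windows, use.names = FALSE)
  if (is.null(windows) || !length(windows)) {
    stop("no occurrences of center base '", ref_base, "' in regions")
  }
  if (!is.null(sample_size) && sample_size < length(windows)) {
    set.seed(seed)
    windows <- windows[sort(sample.int(length(windows), sample_size))]
  }
  structure(
    list(windows = windows, n = length(windows), n_skipped = 0L,
         role = "background", center = ref_base, flank = flank),
    class = "context_windows"
  )
}

#' @export
print.context_windows <- function(x, ...) {
  cat(sprintf("<context_windows> %s: n = %d (center %s, flank %d)\n",
              x$role, x$n, x$center, x$flank))
  invisible(x)
}

#' Signed binomial log-odds of over/under-representation
#'
#' For observed fraction above the background probability, the tail
#' probability is `P = Pr[X >= k | Binomial(n, p)]` and the height is
#' `log10((1 - P) / P)` (positive); below, `P = Pr[X <= k]` and the height is
#' negated. At `k / n == p` the height is 0 by convention. Tail sums are
#' computed exactly in log space (no normal approximation) and no capping is
#' applied. Vectorized over `k`, `n`, `p`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials.
#' @param p Background probability in (0, 1).
#' @return Signed log-odds height(s).
#' @export
binomial_logodds <- function(k, n, p) {
  len <- max(length(k), length(n), length(p))
  k <- rep_len(k, len); n <- rep_len(n, len); p <- rep_len(p, len)
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  out <- numeric(len)
  over <- k / n > p
  under <- k / n < p
  # log tail probabilities, natural log
  lp <- numeric(len)
  lp[over] <- pbinom(k[over] - 1L, n[over], p[over], lower.tail = FALSE,
                     log.p = TRUE)
  lp[under] <- pbinom(k[under], n[under], p[under], lower.tail = TRUE,
                      log.p = TRUE)
  sel <- over | under
  # log10((1-P)/P) = (log1p(-P) - log(P)) / log(10)
  h <- (log1p(-exp(lp[sel])) - lp[sel]) / log(10)
  out[sel] <- h * ifelse(over[sel], 1, -1)
  out
}

#' Bonferroni-corrected log-odds significance threshold
#'
#' The family-wise alpha is divided by the number of tested cells
#' (positions x bases); the threshold is the log-odds value whose tail
#' probability equals the corrected alpha. With the defaults (14 variable
#' positions x 4 bases = 56 tests at alpha 0.05) this gives 3.05.
#'
#' @param alpha Family-wise significance level.
#' @param n_positions Variable positions tested (default 14).
#' @param n_bases Bases tested per position (default 4).
#' @return The positive log-odds threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_positions = 14L,
                                 n_bases = 4L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n_tests <- n_positions * n_bases
  if (n_tests < 1) stop("need at least one test")
  a <- alpha / n_tests
  log10((1 - a) / a)
}

window_base_counts <- function(windows, flank) {
  width <- 2L * flank + 1L
  m <- matrix(0L, nrow = width, ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(width)) {
    tab <- table(factor(substr(windows, j, j), levels = DNA_BASES))
    m[j, ] <- as.integer(tab)
  }
  m
}

#' Probability-logo matrix of positional base enrichment
#'
#' For every position except the fixed center and every base, computes the
#' signed binomial log-odds of the foreground count against the background
#' positional base frequency, flags cells beyond the Bonferroni threshold,
#' and reports the foreground percentage per cell. Background frequencies of
#' zero with non-zero foreground are floored at `1 / (n_bg + 1)` with a
#' warning.
#'
#' @param fg,bg `context_windows` with the same width and center base.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `plogo` object: `$table` (position, base, k, n, p,
#'   frequency_pct, height, significant), `$threshold`, `$n_fg`, `$n_bg`.
#' @export
plogo_matrix <- function(fg, bg, alpha = 0.05) {
  if (fg$flank != bg$flank) stop("foreground/background width mismatch")
  if (fg$center != bg$center) stop("foreground/background center mismatch")
  flank <- fg$flank
  if (fg$n == 0L) stop("empty foreground window set")
  fgc <- window_base_counts(fg$windows, flank)
  bgc <- window_base_counts(bg$windows, flank)
  width <- 2L * flank + 1L
  positions <- seq_len(width) - flank - 1L    # -flank .. +flank
  keep <- positions != 0L
  rows <- expand.grid(base = DNA_BASES, position = positions[keep],
                      stringsAsFactors = FALSE)
  rows <- rows[, c("position", "base")]
  j <- rows$position + flank + 1L
  bi <- match(rows$base, DNA_BASES)
  k <- fgc[cbind(j, bi)]
  p <- bgc[cbind(j, bi)] / bg$n
  floor_p <- 1 / (bg$n + 1)
  zero_bg <- p <= 0 & k > 0
  if (any(zero_bg)) {
    warning(sum(zero_bg), " cell(s) with zero background frequency; ",
            "flooring p at 1/(n_bg + 1)")
  }
  p[p <= 0] <- floor_p
  p[p >= 1] <- 1 - floor_p
  height <- binomial_logodds(k, fg$n, p)
  thr <- bonferroni_threshold(alpha, n_positions = sum(keep), n_bases = 4L)
  tab <- data.frame(
    position = rows$position, base = rows$base, k = k, n = fg$n, p = p,
    frequency_pct = 100 * k / fg$n, height = height,
    significant = abs(height) >= thr, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, threshold = thr, alpha = alpha, n_fg = fg$n,
         n_bg = bg$n, center = fg$center, flank = flank),
    class = "plogo"
  )
}

#' @export
print.plogo <- function(x, ...) {
  cat(sprintf(
    "<plogo> center %s, n(fg) = %d, n(bg) = %d, threshold +/- %.2f\n",
    x$center, x$n_fg, x$n_bg, x$threshold
  ))
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant cells:\n")
    sig <- sig[order(-abs(sig$height)), ]
    for (i in seq_len(min(nrow(sig), 10L))) {
      cat(sprintf("  %s at %+d: %.1f%%, height %.2f\n", sig$base[i],
                  sig$position[i], sig$frequency_pct[i], sig$height[i]))
    }
  } else cat("no significant cells\n")
  invisible(x)
}

#' @method summary plogo
#' @export
summary.plogo <- function(object, ...) {
  object$table[order(object$table$position,
                     object$table$base), , drop = FALSE]
}

#' Probability-logo plot
#'
#' Base letters drawn at their signed log-odds heights per position, with the
#' Bonferroni threshold as horizontal bars and the fixed center base marked.
#'
#' @param x A `plogo`.
#' @param ... Passed to [graphics::plot()].
#' @method plot plogo
#' @export
plot.plogo <- function(x, ...) {
  tab <- x$table
  ylim <- range(c(tab$height, x$threshold, -x$threshold)) * 1.1
  graphics::plot(NA, xlim = c(-x$flank - 0.5, x$flank + 0.5), ylim = ylim,
                 xlab = "position relative to fixed base",
                 ylab = "log-odds", ...)
  graphics::abline(h = c(-x$threshold, x$threshold), col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey")
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  for (pos in unique(tab$position)) {
    sub <- tab[tab$position == pos, ]
    up <- sub[sub$height > 0, ]; up <- up[order(up$height), ]
    dn <- sub[sub$height < 0, ]; dn <- dn[order(-dn$height), ]
    y <- 0
    for (i in seq_len(nrow(up))) {
      graphics::text(pos, y + up$height[i] / 2, up$base[i],
                     col = cols[up$base[i]], font = 2,
                     cex = 0.6 + 0.4 * up$significant[i])
      y <- y + up$height[i]
    }
    y <- 0
    for (i in seq_len(nrow(dn))) {
      graphics::text(pos, y + dn$height[i] / 2, dn$base[i],
                     col = cols[dn$base[i]], font = 2,
                     cex = 0.6 + 0.4 * dn$significant[i])
      y <- y + dn$height[i]
    }
  }
  graphics::text(0, 0, x$center, font = 2, col = "grey40")
  invisible(x)
}

#' Write a pLOGO table as TSV
#'
#' @param x A `plogo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plogo_tsv <- function(x, path) {
  write.table(summary(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
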