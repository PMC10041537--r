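#' Reporter-assay mutant frequency
#'
#' The mutant frequency of an animal is the ratio of its total
#' 6-thioguanine-resistant colonies to its average chloramphenicol-resistant
#' (titer) colonies.
#'
#' @param tg_resistant Total selection-resistant colonies, or a data frame
#'   with columns `tg_resistant` and `cm_resistant_mean`.
#' @param cm_resistant_mean Average titer colonies (must be > 0).
#' @return Mutant frequency (vectorized); for data-frame input, the input
#'   with an `mf` column appended.
#' @export
mutant_frequency <- function(tg_resistant, cm_resistant_mean = NULL) {
  if (is.data.frame(tg_resistant)) {
    df <- tg_resistant
    df$mf <- mutant_frequency(df$tg_resistant, df$cm_resistant_mean)
    return(df)
  }
  if (any(cm_resistant_mean <= 0)) {
    stop("cm_resistant_mean must be positive")
  }
  if (any(tg_resistant < 0)) stop("colony counts must be non-negative")
  tg_resistant / cm_resistant_mean
}

#' Fold change of group mean mutant frequencies
#'
#' @param treated,control Numeric vectors of per-animal mutant frequencies.
#' @return `mean(treated) / mean(control)`.
#' @export
fold_change <- function(treated, control) {
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be positive")
  mean(treated) / mc
}

#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes U from midrank sums and the exact two-sided p-value by
#' enumerating all `choose(na + nb, na)` group labelings of the pooled
#' sample (ties handled by midranks throughout). The two-sided p is twice
#' the smaller tail, capped at 1 -- the definition under which two groups of
#' five with complete separation give p = 0.0079 and a single crossing gives
#' p = 0.0159. Group sizes are limited to 12 for enumeration.
#'
#' @param a,b Numeric vectors (non-empty, at most 12 each).
#' @return An object of class `htest` with `statistic` (U for group `a`) and
#'   `p.value`.
#' @export
mann_whitney_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  if (na > 12L || nb > 12L) {
    stop("exact enumeration supports at most 12 observations per group")
  }
  r <- rank(c(a, b))            # midranks
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  rs <- combn(na + nb, na, FUN = function(idx) sum(r[idx]))
  us <- rs - na * (na + 1) / 2
  eps <- 1e-9
  lo <- mean(us <= u_obs + eps)
  hi <- mean(us >= u_obs - eps)
  p <- min(1, 2 * min(lo, hi))
  structure(
    list(
      statistic = c(U = u_obs), p.value = p,
      method = "Exact Mann-Whitney U test (full enumeration, midranks)",
      data.name = paste(deparse(substitute(a)), "and",
                        deparse(substitute(b))),
      alternative = "two.sided"
    ),
    class = "htest"
  )
}

#' Summarize a reporter-assay colony-count table
#'
#' Computes per-animal mutant frequencies, per-group means, the fold change
#' of every group against a reference group, and exact Mann-Whitney
#' comparisons against that reference.
#'
#' @param counts Data frame with columns `animal`, `group`, `tg_resistant`,
#'   `cm_resistant_mean` (as read from a colony-count TSV).
#' @param reference Reference (control) group label; defaults to the first
#'   group in the table.
#' @return A `gpt_assay` object: `$animals` (with `mf`), `$groups` (group,
#'   n, mean_mf, fold_change, U, p_value).
#' @export
gpt_assay_stats <- function(counts, reference = NULL) {
  need <- c("animal", "group", "tg_resistant", "cm_resistant_mean")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  counts <- mutant_frequency(counts)
  groups <- unique(counts$group)
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("reference group not present")
  ref_mf <- counts$mf[counts$group == reference]
  rows <- lapply(groups, function(g) {
    mf <- counts$mf[counts$group == g]
    if (g == reference) {
      data.frame(group = g, n = length(mf), mean_mf = mean(mf),
                 fold_change = 1, U = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ht <- mann_whitney_exact(mf, ref_mf)
      data.frame(group = g, n = length(mf), mean_mf = mean(mf),
                 fold_change = fold_change(mf, ref_mf),
                 U = unname(ht$statistic), p_value = ht$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  structure(
    list(animals = counts, groups = do.call(rbind, rows),
         reference = reference),
    class = "gpt_assay"
  )
}

#' @export
print.gpt_assay <- function(x, ...) {
  cat(sprintf("<gpt_assay> reference group: %s\n", x$reference))
  g <- x$groups
  g$mean_mf <- sprintf("%.2fe-6", g$mean_mf * 1e6)
  print(g, row.names = FALSE)
  invisible(x)
}
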