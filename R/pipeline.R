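#' Assemble a pipeline configuration
#'
#' Collects all stage parameters with the package defaults: trim bases 1-8
#' and 120-137, 300-350 bp fragments, 15-base logo windows (flank 7), alpha
#' 0.05, minimum family size 3, consensus threshold 0.7. All randomness
#' flows from the single `seed`.
#'
#' @param reference Path to a reference FASTA, or a list of
#'   `reference_region` objects.
#' @param out_dir Output directory (created if missing).
#' @param fastq1,fastq2 Optional existing tagged read files; when `NULL` the
#'   simulate stage generates them (requires `sim`).
#' @param sim Optional `simulation_config` for the simulate stage.
#' @param signatures Optional named character vector of signature TSV paths
#'   for the comparison stage.
#' @param min_family_size,consensus_threshold,trim,reject_on_disagreement
#'   Consensus parameters (see [duplex_consensus()]).
#' @param seed_length,min_identity Placement parameters (see
#'   [align_dcs_set()]).
#' @param dedup_by Unique-mutation key (see [unique_mutations()]).
#' @param ref_base,alt_base,flank,alpha Probability-logo parameters.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(reference, out_dir, fastq1 = NULL, fastq2 = NULL,
                            sim = NULL, signatures = NULL,
                            min_family_size = 3L, consensus_threshold = 0.7,
                            trim = list(c(1L, 8L), c(120L, 137L)),
                            reject_on_disagreement = FALSE,
                            seed_length = 20L, min_identity = 0.9,
                            dedup_by = "position_alt",
                            ref_base = "G", alt_base = "A", flank = 7L,
                            alpha = 0.05, seed = 1L) {
  if (is.character(reference)) reference <- load_reference(reference)
  if (inherits(reference, "reference_region")) reference <- list(reference)
  if (is.null(fastq1) != is.null(fastq2)) {
    stop("provide both fastq1 and fastq2, or neither")
  }
  if (is.null(fastq1) && is.null(sim)) {
    stop("either existing fastq files or a simulation config is required")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(
    list(
      reference = reference, out_dir = out_dir, fastq1 = fastq1,
      fastq2 = fastq2, sim = sim, signatures = signatures,
      min_family_size = as.integer(min_family_size),
      consensus_threshold = consensus_threshold, trim = trim,
      reject_on_disagreement = reject_on_disagreement,
      seed_length = as.integer(seed_length), min_identity = min_identity,
      dedup_by = dedup_by, ref_base = ref_base, alt_base = alt_base,
      flank = as.integer(flank), alpha = alpha, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

serialize_config <- function(config, path) {
  flat <- config
  flat$reference <- paste(vapply(config$reference, `[[`, "", "name"),
                          collapse = ",")
  flat$sim <- if (is.null(config$sim)) "none" else
    paste0("n_molecules=", config$sim$n_molecules,
           ";mutation_rate=", config$sim$mutation_rate,
           ";per_base_error_rate=", config$sim$per_base_error_rate,
           ";seed=", config$sim$seed)
  flat$trim <- paste(vapply(config$trim, function(r)
    paste(r, collapse = "-"), character(1)), collapse = ",")
  flat$signatures <- if (is.null(config$signatures)) "none" else
    paste(config$signatures, collapse = ",")
  lines <- vapply(names(flat), function(k)
    paste0(k, " = ", paste(format(flat[[k]]), collapse = " ")), character(1))
  writeLines(lines, path)
}

#' Run the full duplex-spectrum pipeline
#'
#' Executes the stages in order -- simulate (when configured), duplex
#' consensus, placement and mutation calling, spectrum construction and
#' normalization, signature comparison (when signatures are given), and
#' probability-logo enrichment -- writing each stage's artifacts and a run
#' manifest of filtering counts to the output directory. With
#' `resume = TRUE`, stages whose outputs already exist are skipped and their
#' on-disk intermediates reused.
#'
#' @param config A `pipeline_config`.
#' @param resume Reuse existing stage outputs.
#' @return A `pipeline_result` list with the main in-memory objects
#'   (consensus report, mutations, spectrum, plogo, similarity) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  serialize_config(config, file.path(out, "config.txt"))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("duplexspectra")))
  region <- config$reference[[1]]

  # --- simulate ---------------------------------------------------------
  fq1 <- config$fastq1; fq2 <- config$fastq2
  truth <- NULL
  if (is.null(fq1)) {
    fq1 <- file.path(out, "reads_R1.fastq")
    fq2 <- file.path(out, "reads_R2.fastq")
    truth_path <- file.path(out, "truth.tsv")
    if (!(resume && file.exists(fq1) && file.exists(fq2))) {
      sim <- config$sim
      sim$seed <- config$seed
      mols <- simulate_molecules(sim, region)
      fam <- simulate_reads(mols, sim, region, fq1, fq2)
      write_truth(mols, truth_path)
      truth <- list(molecules = mols, families = fam)
      manifest$molecules_simulated <- nrow(mols$molecules)
      manifest$true_mutations_injected <- nrow(mols$mutations)
    }
  }

  # --- consensus --------------------------------------------------------
  mut_path <- file.path(out, "unique_mutations.tsv")
  dcs_path <- file.path(out, "dcs.fastq")
  if (resume && file.exists(mut_path)) {
    unique_muts <- read.delim(mut_path, stringsAsFactors = FALSE)
    unique_muts$pos <- unique_muts$pos - 1L
    cons <- NULL
  } else {
    rl <- if (!is.null(config$sim)) config$sim$read_length else 137L
    tl <- if (!is.null(config$sim)) config$sim$tag_length else 12L
    cons <- duplex_consensus(
      fq1, fq2, min_family_size = config$min_family_size,
      consensus_threshold = config$consensus_threshold, trim = config$trim,
      reject_on_disagreement = config$reject_on_disagreement,
      tag_length = tl, read_length = rl
    )
    write_dcs_fastq(cons, dcs_path)
    manifest <- c(manifest, as.list(cons$report))

    # --- placement + calling -------------------------------------------
    placed <- align_dcs_set(cons, config$reference,
                            seed_length = config$seed_length,
                            min_identity = config$min_identity)
    manifest$dcs_mapped <- nrow(placed$placements)
    manifest$dcs_unmapped <- placed$n_unmapped
    cols <- pileup(placed, config$reference)
    calls <- call_mutations(cols, config$reference)
    unique_muts <- unique_mutations(calls, dedup_by = config$dedup_by)
    manifest$mutation_calls <- nrow(calls)
    manifest$unique_mutations <- nrow(unique_muts)
    write_mutations_tsv(unique_muts, mut_path)
    write_mutations_vcf(unique_muts, file.path(out, "unique_mutations.vcf"))
  }

  # --- spectrum ---------------------------------------------------------
  comp <- trinucleotide_composition(config$reference)
  write_composition(comp, file.path(out, "composition.tsv"))
  spec <- build_spectrum(unique_muts, meta = list(sample = basename(out)))
  nspec <- normalize_spectrum(spec, comp)
  write_spectrum(nspec, file.path(out, "spectrum.tsv"))

  simmat <- NULL
  if (!is.null(config$signatures)) {
    sigs <- lapply(config$signatures, read_signature)
    names(sigs) <- names(config$signatures)
    simmat <- similarity_matrix(list(sample = nspec), signatures = sigs)
    write.table(simmat$values, file.path(out, "cosine_matrix.tsv"),
                sep = "\t", quote = FALSE)
  }

  # --- probability logo -------------------------------------------------
  plg <- NULL
  fgw <- extract_foreground_windows(unique_muts, config$reference,
                                    ref_base = config$ref_base,
                                    alt_base = config$alt_base,
                                    flank = config$flank)
  if (fgw$n > 0) {
    bgw <- extract_background_windows(config$reference,
                                      ref_base = config$ref_base,
                                      flank = config$flank)
    plg <- plogo_matrix(fgw, bgw, alpha = config$alpha)
    write_plogo_tsv(plg, file.path(out, "plogo.tsv"))
  }

  writeLines(vapply(names(manifest), function(k)
    paste0(k, "\t", format(manifest[[k]])), character(1)),
    file.path(out, "manifest.tsv"))

  structure(
    list(out_dir = out, manifest = manifest, consensus = cons,
         mutations = unique_muts, spectrum = nspec, similarity = simmat,
         plogo = plg, truth = truth),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s\n", x$out_dir))
  cat(sprintf("  unique mutations: %d\n", nrow(x$mutations)))
  if (!is.null(x$plogo)) {
    cat(sprintf("  plogo n(fg) = %d, n(bg) = %d\n", x$plogo$n_fg,
                x$plogo$n_bg))
  }
  invisible(x)
}
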