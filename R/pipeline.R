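## End-to-end orchestration: read inputs, call the methylome per condition,
## map sites to genes, run both expression contrasts, integrate, profile
## duplex stability, screen ortholog pairs, and write a structured report.
##
## The package is a library, not a shell tool: run_config()/run_all() are
## the entry points, overridable field by field; a flat key-value config
## file can seed the same structure.

#' Assemble and validate a pipeline run configuration
#'
#' All thresholds are explicit here and echoed in the run report (no silent
#' defaults).  Input files are checked up front and every missing path is
#' reported in one error.
#'
#' @param genome Genome FASTA path.
#' @param annotation Gene annotation path (TSV or GFF3).
#' @param kinetics Named character vector of kinetics TSVs, one per
#'   condition.
#' @param transcript Transcript expression matrix TSV.
#' @param proteome Optional proteome matrix TSV (`NULL` to skip the protein
#'   level).
#' @param ortholog_manifest Optional two-column TSV (`gene`, `path`) of
#'   paired codon-alignment FASTAs (`NULL` to skip the selection screen).
#' @param control Control condition label.
#' @param treatments Treatment condition labels contrasted against the
#'   control.
#' @param min_coverage,min_ipd_ratio Modification-calling thresholds.
#' @param alpha Transcript raw-p cutoff.
#' @param q_alpha Proteome BH q cutoff.
#' @param upstream_len Upstream window length (bp).
#' @param window_size Duplex-stability window (bp; shrunk to the genome if
#'   larger).
#' @param motif_pattern,motif_offset Recognition motif to scan.
#' @param out_dir Output directory.
#' @param seed Seed echoed into the report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome, annotation, kinetics, transcript,
                       proteome = NULL, ortholog_manifest = NULL,
                       control = "T26", treatments = c("T4", "UV"),
                       min_coverage = 25, min_ipd_ratio = 2.0,
                       alpha = 0.05, q_alpha = 0.05, upstream_len = 500L,
                       window_size = 100000L,
                       motif_pattern = "CTAYNNNNNNNNTRTC",
                       motif_offset = 2L,
                       out_dir = "methlink_run", seed = 1L) {
  if (is.null(names(kinetics)) || any(names(kinetics) == ""))
    stop("kinetics paths must be named by condition")
  cfg <- structure(list(
    genome = genome, annotation = annotation, kinetics = kinetics,
    transcript = transcript, proteome = proteome,
    ortholog_manifest = ortholog_manifest, control = control,
    treatments = treatments, min_coverage = min_coverage,
    min_ipd_ratio = min_ipd_ratio, alpha = alpha, q_alpha = q_alpha,
    upstream_len = as.integer(upstream_len),
    window_size = as.integer(window_size), motif_pattern = motif_pattern,
    motif_offset = as.integer(motif_offset), out_dir = out_dir,
    seed = as.integer(seed)), class = "run_config")
  required <- c(genome = genome, annotation = annotation, kinetics,
                transcript = transcript)
  optional <- c(proteome = proteome, ortholog_manifest = ortholog_manifest)
  missing <- c(required[!file.exists(required)],
               optional[!vapply(optional, file.exists, logical(1L))])
  if (length(missing))
    stop("missing input file(s):\n  ",
         paste(sprintf("%s: %s", names(missing), missing), collapse = "\n  "))
  if (!control %in% names(kinetics))
    stop("control condition has no kinetics table")
  cfg
}

#' Run the full pipeline
#'
#' Stages, in dependency order: genome and annotation input; motif scan;
#' per-condition modification calling, methylome summary and feature
#' assignment; transcript and (when provided) proteome differential
#' expression per treatment; tri-level integration with co-occurrence
#' summaries and methylation deltas against the control; duplex-stability
#' window profile; Ka/Ks selection screen (when a manifest is provided).
#' Every stage writes its table under `out_dir` so partial re-runs can
#' reload intermediates, and the JSON report echoes every threshold; the
#' report body is deterministic for a fixed config (no timestamps), so
#' re-running an unchanged config reproduces it byte for byte.
#'
#' @param config A [run_config()].
#' @return The run report (named list), invisibly; also written as
#'   `report.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  report <- list(package = "methlink",
                 version = as.character(utils::packageVersion("methlink")),
                 parameters = unclass(config), stages = list())

  genome <- read_fasta(config$genome)
  genes <- read_annotation(config$annotation)
  report$stages$inputs <- list(genome_id = genome$id,
                               genome_length = genome$length,
                               n_genes = nrow(genes))

  motif <- iupac_motif(config$motif_pattern, config$motif_offset)
  census <- motif_census(genome, motif)
  write_bed(census$hits, out("motif_hits.bed"), seqid = genome$id)
  report$stages$motif_scan <- list(
    pattern = motif$pattern,
    forward_both_patterns = census$forward_both_patterns,
    both_strand_dedup = census$both_strand_dedup)

  params <- call_params(config$min_coverage, config$min_ipd_ratio)
  conditions <- names(config$kinetics)
  calls <- list(); summaries <- list(); assignments <- list()
  profiles <- list()
  for (cond in conditions) {
    kin <- read_kinetics(config$kinetics[[cond]])
    cl <- call_modifications(kin, params)
    calls[[cond]] <- cl
    summaries[[cond]] <- summarize_calls(cl, genome)
    assignments[[cond]] <- assign_sites(cl, genes, genome,
                                        config$upstream_len)
    profiles[[cond]] <- gene_methylation_profile(cl, genes, genome,
                                                 config$upstream_len)
    write_calls_gff3(cl, out("calls_%s.gff3", cond), seqid = genome$id)
    write_calls_bed(cl, out("calls_%s.bed", cond), seqid = genome$id)
    write_assignments_tsv(assignments[[cond]],
                          out("assignments_%s.tsv", cond))
    s <- summaries[[cond]]
    mmf <- motif_methylation_fraction(census$hits, cl)
    report$stages$methylome[[cond]] <- list(
      n_calls = s$n_total, n_positions = s$n_positions,
      n_m6A = s$n_m6A, n_m4C = s$n_m4C,
      pct_total = s$pct_total, pct_m6A = s$pct_m6A, pct_m4C = s$pct_m4C,
      pct_in_gene_or_upstream = if (nrow(assignments[[cond]]))
        fraction_in_gene_and_upstream(assignments[[cond]]) else NA,
      pct_genes_methylated =
        percent_genes_methylated(assignments[[cond]], genes),
      motif_methylated_fraction = mmf$pooled,
      strand_balance = strand_balance(cl))
  }

  tmat <- read_expression(config$transcript)
  pmat <- if (!is.null(config$proteome))
    proteome_preprocess(read_expression(config$proteome)) else NULL
  for (trt in config$treatments) {
    tde <- transcript_de(tmat, trt, config$control, alpha = config$alpha)
    write_de_tsv(tde, out("de_transcript_%s.tsv", trt))
    pde <- NULL
    if (!is.null(pmat)) {
      pde <- proteome_de(pmat, trt, config$control, q_alpha = config$q_alpha)
      write_de_tsv(pde, out("de_proteome_%s.tsv", trt))
    }
    tri <- build_trilevel(profiles[[trt]], tde, pde, genes)
    write.table(tri, out("trilevel_%s.tsv", trt), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cooc <- co_occurrence_summary(tri)
    write_summary_json(cooc, out("co_occurrence_%s.json", trt))
    deltas <- methylation_deltas(summaries[[trt]],
                                 summaries[[config$control]])
    report$stages$integration[[trt]] <- list(
      n_transcript_significant = sum(tde$significant),
      n_protein_significant = if (is.null(pde)) NA else
        sum(pde$significant),
      trilevel_available = !is.null(pde),
      pct_methylated_down_all_genes = cooc$pct_methylated_down_all_genes,
      pct_methylated_up_all_genes = cooc$pct_methylated_up_all_genes,
      pct_trilevel = if (is.null(pde)) NA else cooc$pct_trilevel,
      updown_fractions = cooc$updown_fractions,
      methylation_deltas = deltas)
  }

  window <- min(config$window_size, genome$length)
  prof <- window_profile(genome, window = window)
  write_bedgraph(prof, out("melting_profile.bedgraph"), seqid = genome$id)
  write_circos_track(
    data.frame(start = prof$window_start,
               end = prof$window_start + prof$window_size,
               value = -prof$mean_dG37),
    out("melting_profile_circos.txt"), seqid = genome$id)
  report$stages$thermo <- list(window = window, n_windows = nrow(prof),
                               mean_dG37 = mean(prof$mean_dG37, na.rm = TRUE))

  if (!is.null(config$ortholog_manifest)) {
    man <- read.delim(config$ortholog_manifest, stringsAsFactors = FALSE)
    sets <- split(man$path, man$gene)
    gene_sets <- lapply(sets, function(p) lapply(p, read_codon_alignment))
    screen <- selection_screen(gene_sets)
    write.table(screen, out("kaks_screen.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$stages$kaks <- list(
      n_genes = nrow(screen),
      n_purifying = sum(screen$purifying, na.rm = TRUE),
      median_of_medians = median(screen$median, na.rm = TRUE))
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
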