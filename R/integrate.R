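## Three-tier co-occurrence analysis: join per-condition gene methylation
## profiles with transcript and protein differential-expression calls.

#' Build the per-gene tri-level record table
#'
#' One row per annotated gene, joining the treatment condition's methylation
#' profile with the transcript and protein contrasts against the control.
#' Genes absent from an assay carry `NA` (absent, not zero).  DE features
#' whose identifiers are not in the gene universe are excluded with a
#' warning and recorded in the `excluded` attribute.
#'
#' @param profile Gene methylation profile of the treatment condition, from
#'   [gene_methylation_profile()].
#' @param transcript Result of [transcript_de()] for the same contrast, or
#'   `NULL` when the assay is unavailable.
#' @param protein Result of [proteome_de()], or `NULL`.
#' @param genes Gene table defining the locus-tag universe.
#' @return Data frame of class `trilevel` with methylation counts and
#'   booleans (`methylated`, `m6A_methylated`, `m4C_methylated`) and the
#'   joined `transcript_*` / `protein_*` statistics.
#' @export
build_trilevel <- function(profile, transcript, protein, genes) {
  universe <- genes$locus_tag
  out <- data.frame(locus_tag = universe, stringsAsFactors = FALSE)
  pr <- profile[match(universe, profile$locus_tag), , drop = FALSE]
  for (col in c("n_m6A_body", "n_m4C_body", "n_m6A_upstream",
                "n_m4C_upstream")) {
    v <- pr[[col]]
    v[is.na(v)] <- 0L
    out[[col]] <- v
  }
  out$m6A_methylated <- (out$n_m6A_body + out$n_m6A_upstream) > 0L
  out$m4C_methylated <- (out$n_m4C_body + out$n_m4C_upstream) > 0L
  out$methylated <- out$m6A_methylated | out$m4C_methylated

  excluded <- character(0)
  join_de <- function(de, prefix) {
    if (is.null(de)) {
      out[[paste0(prefix, "_log2fc")]] <<- rep(NA_real_, nrow(out))
      out[[paste0(prefix, "_p")]] <<- rep(NA_real_, nrow(out))
      out[[paste0(prefix, "_q")]] <<- rep(NA_real_, nrow(out))
      out[[paste0(prefix, "_significant")]] <<- rep(NA, nrow(out))
      return(invisible(NULL))
    }
    stray <- setdiff(de$feature_id, universe)
    if (length(stray)) {
      warning(sprintf("%d %s feature(s) not in the gene universe excluded",
                      length(stray), prefix))
      excluded <<- union(excluded, stray)
      de <- de[de$feature_id %in% universe, , drop = FALSE]
    }
    ix <- match(universe, de$feature_id)
    out[[paste0(prefix, "_log2fc")]] <<- de$log2fc[ix]
    out[[paste0(prefix, "_p")]] <<- de$p_value[ix]
    out[[paste0(prefix, "_q")]] <<- de$q_value[ix]
    sig <- de$significant[ix]
    sig[!is.na(ix) & !de$tested[ix]] <- NA
    out[[paste0(prefix, "_significant")]] <<- sig
  }
  join_de(transcript, "transcript")
  join_de(protein, "protein")
  attr(out, "excluded") <- excluded
  class(out) <- c("trilevel", "data.frame")
  out
}

.frac_or_flag <- function(num, den) {
  if (den == 0) list(value = NA_real_, defined = FALSE)
  else list(value = num / den, defined = TRUE)
}

#' Co-occurrence summary between methylation and expression
#'
#' Emits (a) the percentage of genes down- or up-regulated while methylated
#' (body or upstream), under both the all-genes and the methylated-genes
#' denominator, (b) the percentage of genes traceable at all three levels
#' (methylated, transcript-significant and protein-significant in the same
#' contrast), and (c) up/down fractions among methylation-associated
#' differentially expressed genes split by expression level and
#' modification type (the shape of a published treatment-vs-control
#' variation table, whose up and down fractions sum to 1 within each cell
#' group).  Empty cell groups are reported as undefined flags, never 0/0.
#'
#' @param records Tri-level table from [build_trilevel()].
#' @return A list of class `co_occurrence_summary`.
#' @export
co_occurrence_summary <- function(records) {
  n_genes <- nrow(records)
  if (!n_genes) stop("empty tri-level record set")
  meth <- records$methylated
  t_sig <- !is.na(records$transcript_significant) &
    records$transcript_significant
  p_sig <- !is.na(records$protein_significant) & records$protein_significant
  t_down <- t_sig & records$transcript_log2fc < 0
  t_up <- t_sig & records$transcript_log2fc > 0
  n_meth <- sum(meth)

  pct <- function(x, den) if (den > 0) 100 * x / den else NA_real_
  down_meth <- sum(meth & t_down)
  up_meth <- sum(meth & t_up)

  cells <- list()
  for (level in c("transcript", "protein")) {
    sig <- if (level == "transcript") t_sig else p_sig
    lfc <- records[[paste0(level, "_log2fc")]]
    for (mod in c("m6A", "m4C")) {
      mm <- records[[paste0(mod, "_methylated")]]
      sel <- mm & sig
      n <- sum(sel)
      up <- .frac_or_flag(sum(sel & lfc > 0), n)
      down <- .frac_or_flag(sum(sel & lfc < 0), n)
      cells[[length(cells) + 1L]] <- data.frame(
        level = level, mod_type = mod, n = n,
        up_fraction = up$value, down_fraction = down$value,
        defined = up$defined, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    n_genes = n_genes,
    n_methylated = n_meth,
    pct_methylated_down_all_genes = pct(down_meth, n_genes),
    pct_methylated_up_all_genes = pct(up_meth, n_genes),
    pct_methylated_down_methylated_genes = pct(down_meth, n_meth),
    pct_methylated_up_methylated_genes = pct(up_meth, n_meth),
    pct_trilevel = pct(sum(meth & t_sig & p_sig), n_genes),
    updown_fractions = do.call(rbind, cells)
  ), class = "co_occurrence_summary")
}

#' @export
print.co_occurrence_summary <- function(x, ...) {
  cat(sprintf("<co_occurrence_summary> %d genes, %d methylated\n",
              x$n_genes, x$n_methylated))
  cat(sprintf("  methylated & down: %.2f%% of all genes; tri-level: %.2f%%\n",
              x$pct_methylated_down_all_genes, x$pct_trilevel))
  invisible(x)
}

#' Relative methylation-count change between two conditions
#'
#' Positional (coordinate + strand + mod_type) count deltas of a treatment
#' methylome summary against the control: `(treatment - control) / control`
#' per modification type, signed.
#'
#' @param summary_treatment,summary_control `methylome_summary` objects from
#'   [summarize_calls()].
#' @return Data frame per mod_type with treatment and control counts,
#'   `rel_change` and a `defined` flag (`FALSE` when the control count is
#'   zero).
#' @export
methylation_deltas <- function(summary_treatment, summary_control) {
  rows <- lapply(c("m6A", "m4C"), function(m) {
    ct <- summary_treatment[[paste0("n_", m)]]
    cc <- summary_control[[paste0("n_", m)]]
    data.frame(mod_type = m, n_treatment = ct, n_control = cc,
               rel_change = if (cc > 0) (ct - cc) / cc else NA_real_,
               defined = cc > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a co-occurrence summary as JSON
#'
#' @param summary A `co_occurrence_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a genome track as Circos-ready text
#'
#' Plain `chr start end value` lines for circular-map renderers.
#'
#' @param track Data frame with `start`, `end` and `value` columns.
#' @param path Output path.
#' @param seqid Chromosome name.
#' @return `path`, invisibly.
#' @export
write_circos_track <- function(track, path, seqid = "chr") {
  write.table(data.frame(seqid, track$start, track$end, track$value), path,
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
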