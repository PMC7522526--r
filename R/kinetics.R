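## IPD-ratio computation and m6A/m4C modification calling.
##
## Single-molecule sequencing kinetics respond to template methylation: the
## interpulse duration (IPD) at a modified base is elevated relative to an
## unmodified control.  A position is called modified when its case/control
## IPD ratio and per-strand coverage both clear configurable thresholds.

#' Calling thresholds for kinetic modification detection
#'
#' The coverage rule is strict ("minimum >25x per strand" reads as strictly
#' greater than).  No published IPD-ratio cutoff accompanies the kinetic
#' pipeline this mirrors, so the default ratio threshold of 2.0 is a common
#' kinetic-detection heuristic; it is configurable and echoed in all output
#' metadata.
#'
#' @param min_coverage_per_strand Minimum per-strand read coverage; a record
#'   must exceed this value (default 25).
#' @param min_ipd_ratio Minimum case/control IPD ratio (default 2.0).
#' @param bases Bases considered callable; only adenine (m6A) and cytosine
#'   (m4C) signals are interpreted.
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_coverage_per_strand = 25,
                        min_ipd_ratio = 2.0,
                        bases = c("A", "C")) {
  if (min_coverage_per_strand < 1) stop("min_coverage_per_strand must be >= 1")
  if (min_ipd_ratio <= 1) stop("min_ipd_ratio must be > 1")
  if (!all(bases %in% c("A", "C"))) stop("bases must be a subset of {A, C}")
  structure(list(min_coverage_per_strand = min_coverage_per_strand,
                 min_ipd_ratio = min_ipd_ratio,
                 bases = bases),
            class = "call_params")
}

#' Read a per-position kinetics table
#'
#' Expects a TSV with header columns `position` (0-based), `strand`, `base`,
#' `coverage`, `ipd_case` and `ipd_control`.
#'
#' @param path Input TSV.
#' @return A data frame of kinetics records.
#' @export
read_kinetics <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "strand", "base", "coverage", "ipd_case", "ipd_control")
  if (!all(need %in% names(d)))
    stop("kinetics TSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' Case/control IPD ratios
#'
#' @param records Kinetics data frame (see [read_kinetics()]).
#' @return Numeric vector `ipd_case / ipd_control`, one per record.
#' @export
ipd_ratio <- function(records) {
  zero <- which(records$ipd_control == 0)
  if (length(zero))
    stop(sprintf("undefined IPD ratio (control IPD == 0) at position %d%s",
                 records$position[zero[1L]],
                 if (length(zero) > 1L)
                   sprintf(" and %d more positions", length(zero) - 1L) else ""))
  records$ipd_case / records$ipd_control
}

#' Call m6A/m4C modifications from kinetics records
#'
#' A record yields a call iff its base is callable, its coverage strictly
#' exceeds the per-strand minimum and its IPD ratio reaches the ratio
#' threshold.  Adenine calls are typed m6A, cytosine calls m4C.
#'
#' In the default two-sample design the control IPD comes with each record.
#' Alternatively `expected_ipd` supplies a per-base expected-IPD table
#' (single-sample mode) that replaces the per-record control.
#'
#' @param records Kinetics data frame.
#' @param params A [call_params()] object.
#' @param expected_ipd Optional named numeric vector of expected control
#'   IPDs by base (single-sample mode).
#' @return Data frame of calls with columns `position`, `strand`, `base`,
#'   `mod_type`, `ipd_ratio`, `coverage`, sorted by (position, strand).  The
#'   thresholds used are attached as attribute `params`.
#' @export
call_modifications <- function(records, params = call_params(),
                               expected_ipd = NULL) {
  stopifnot(inherits(params, "call_params"))
  if (!is.null(expected_ipd)) {
    if (is.null(names(expected_ipd)))
      stop("expected_ipd must be named by base")
    records$ipd_control <- unname(expected_ipd[records$base])
  }
  cand <- records[records$base %in% params$bases &
                    records$coverage > params$min_coverage_per_strand, ,
                  drop = FALSE]
  if (nrow(cand)) {
    ratio <- ipd_ratio(cand)
    keep <- ratio >= params$min_ipd_ratio
    cand <- cand[keep, , drop = FALSE]
    ratio <- ratio[keep]
  } else ratio <- numeric(0)
  calls <- data.frame(
    position = as.integer(cand$position),
    strand = as.character(cand$strand),
    base = as.character(cand$base),
    mod_type = ifelse(cand$base == "A", "m6A", "m4C"),
    ipd_ratio = ratio,
    coverage = as.integer(cand$coverage),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$position, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "params") <- params
  calls
}

.complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Summarize a set of modification calls against a genome
#'
#' Computes the counts and percentages of methylated adenines and cytosines
#' (per base over both-strand denominators, and together over the genome's
#' both-strand A+C total), a per-strand breakdown, and both the
#' strand-specific site total and the positionally collapsed total (paired
#' strand calls at one coordinate counted once).
#'
#' @param calls Call table from [call_modifications()].
#' @param genome A `genome_seq`; every call must sit on a genome base
#'   consistent with its own base and strand.
#' @return A list of class `methylome_summary` with elements `n_m6A`,
#'   `n_m4C`, `n_total`, `n_positions`, `pct_m6A`, `pct_m4C`, `pct_total`
#'   and `per_strand` (data frame with per-strand counts and percentages).
#' @export
summarize_calls <- function(calls, genome) {
  stopifnot(inherits(genome, "genome_seq"))
  if (nrow(calls)) {
    fwd <- vapply(calls$position + 1L,
                  function(p) substr(genome$seq, p, p), character(1L))
    expected <- ifelse(calls$strand == "+", calls$base,
                       .complement_base(calls$base))
    bad <- which(fwd != expected)
    if (length(bad))
      stop(sprintf(
        "call/genome base mismatch at position %d: genome '%s', call %s on %s",
        calls$position[bad[1L]], fwd[bad[1L]], calls$base[bad[1L]],
        calls$strand[bad[1L]]))
  }
  comp <- base_composition(genome)
  n_m6A <- sum(calls$mod_type == "m6A")
  n_m4C <- sum(calls$mod_type == "m4C")
  n_total <- nrow(calls)

  ## per-strand denominators: adenines readable on + are forward A, on - are
  ## forward T; cytosines likewise C / G.
  denom <- c(`m6A+` = unname(comp$forward["A"]),
             `m6A-` = unname(comp$forward["T"]),
             `m4C+` = unname(comp$forward["C"]),
             `m4C-` = unname(comp$forward["G"]))
  ps <- expand.grid(mod_type = c("m6A", "m4C"), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  ps$count <- mapply(function(m, s)
    sum(calls$mod_type == m & calls$strand == s), ps$mod_type, ps$strand)
  ps$denominator <- denom[paste0(ps$mod_type, ps$strand)]
  ps$percent <- ifelse(ps$denominator > 0, 100 * ps$count / ps$denominator, NA)

  structure(list(
    n_m6A = n_m6A, n_m4C = n_m4C, n_total = n_total,
    n_positions = length(unique(calls$position)),
    pct_m6A = if (comp$both_strand["A"] > 0)
      100 * n_m6A / comp$both_strand["A"] else NA_real_,
    pct_m4C = if (comp$both_strand["C"] > 0)
      100 * n_m4C / comp$both_strand["C"] else NA_real_,
    pct_total = 100 * n_total / comp$a_plus_c,
    per_strand = ps,
    a_plus_c = comp$a_plus_c,
    params = attr(calls, "params")
  ), class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat(sprintf("<methylome_summary> %d calls (%d positions): %d m6A, %d m4C\n",
              x$n_total, x$n_positions, x$n_m6A, x$n_m4C))
  cat(sprintf("  %% of both-strand A+C methylated: %.4f\n", x$pct_total))
  invisible(x)
}

#' Write modification calls as GFF3
#'
#' Mirrors the PacBio `modifications.gff` dialect: one `modified_DNA_base`
#' feature per call (1-based inclusive coordinates) with `mod_type`,
#' `ipd_ratio` and `coverage` attributes, plus the thresholds used in a
#' header pragma.
#'
#' @param calls Call table from [call_modifications()].
#' @param path Output path.
#' @param seqid Sequence name for column 1.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_calls_gff3 <- function(calls, path, seqid = "chr", source = "methlink") {
  p <- attr(calls, "params")
  hdr <- c("##gff-version 3",
           if (!is.null(p)) sprintf(
             "#min_coverage_per_strand=%s;min_ipd_ratio=%s",
             p$min_coverage_per_strand, p$min_ipd_ratio))
  lines <- c(hdr, if (nrow(calls)) sprintf(
    "%s\t%s\tmodified_DNA_base\t%d\t%d\t.\t%s\t.\tmod_type=%s;ipd_ratio=%.4f;coverage=%d",
    seqid, source, calls$position + 1L, calls$position + 1L, calls$strand,
    calls$mod_type, calls$ipd_ratio, calls$coverage))
  writeLines(lines, path)
  invisible(path)
}

#' Write modification calls as BED6
#'
#' @inheritParams write_calls_gff3
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, seqid = "chr") {
  bed <- data.frame(chrom = seqid, start = calls$position,
                    end = calls$position + 1L, name = calls$mod_type,
                    score = 0L, strand = calls$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
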