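## Assignment of modification calls to gene bodies, 500-bp upstream windows
## or intergenic space, and the gene-level methylation summaries.

## Expand (possibly wrapping) 0-based half-open intervals into IRanges
## pieces on [0, L).  Returns a data.frame(idx, s, e) of non-wrapping pieces.
.normalize_intervals <- function(start, end, L, circular) {
  idx <- seq_along(start)
  width <- end - start
  if (any(width <= 0)) stop("intervals must have positive width")
  if (any(width > L)) stop("interval wider than genome")
  s0 <- if (circular) start %% L else pmax(start, 0L)
  e0 <- s0 + width
  if (!circular) e0 <- pmin(e0, L)
  keep <- e0 > s0
  pieces <- data.frame(idx = idx[keep], s = s0[keep], e = pmin(e0[keep], L))
  over <- which(e0 > L)
  if (length(over) && circular)
    pieces <- rbind(pieces, data.frame(idx = idx[over], s = 0L,
                                       e = e0[over] - L))
  pieces
}

## For each position, the interval indices containing it (list of integer
## vectors), via IRanges overlap.
.positions_in <- function(positions, pieces) {
  res <- vector("list", length(positions))
  if (!nrow(pieces) || !length(positions)) return(res)
  q <- IRanges::IRanges(start = positions + 1L, width = 1L)
  s <- IRanges::IRanges(start = pieces$s + 1L, end = pieces$e)
  ov <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  for (i in seq_along(qh))
    res[[qh[i]]] <- c(res[[qh[i]]], pieces$idx[sh[i]])
  lapply(res, unique)
}

.gene_windows <- function(genes, genome, upstream_len) {
  L <- genome$length
  up_start <- ifelse(genes$strand == "+", genes$start - upstream_len,
                     genes$end)
  body <- .normalize_intervals(genes$start, genes$end, L, genome$circular)
  up <- if (upstream_len > 0)
    .normalize_intervals(up_start, up_start + upstream_len, L,
                         genome$circular)
  else data.frame(idx = integer(0), s = integer(0), e = integer(0))
  list(body = body, upstream = up)
}

#' Assign modification calls to genomic feature categories
#'
#' Each call is categorised as `gene_body` when its position lies inside any
#' gene's `[start, end)` span, otherwise `upstream500` when it lies in the
#' fixed-length window 5' of any gene's start (on the gene's own strand; for
#' minus-strand genes the window is `[end, end + upstream_len)` in forward
#' coordinates), otherwise `intergenic`.  Upstream windows are full fixed
#' windows, not truncated at neighbouring genes.  The strand of the call is
#' ignored: a methylation on either strand within a gene's span counts for
#' that gene.  Category precedence is gene_body > upstream500, but a call in
#' one gene's body and another gene's upstream window is associated with
#' both in the locus-tag detail.
#'
#' @param calls Call table (needs `position`, `strand`, `mod_type`).
#' @param genes Gene table from [gene_table()].
#' @param genome A `genome_seq` (supplies length and circularity).
#' @param upstream_len Upstream window length in bp (default 500).
#' @return Data frame with the call columns plus `category`, `locus_tags`
#'   (semicolon-joined association detail), `body_locus_tags` and
#'   `upstream_locus_tags`.
#' @export
assign_sites <- function(calls, genes, genome, upstream_len = 500L) {
  stopifnot(inherits(genome, "genome_seq"), upstream_len >= 0)
  if (!nrow(calls)) {
    out <- cbind(calls,
                 data.frame(category = character(0),
                            locus_tags = character(0),
                            body_locus_tags = character(0),
                            upstream_locus_tags = character(0),
                            stringsAsFactors = FALSE))
    return(out)
  }
  win <- .gene_windows(genes, genome, upstream_len)
  in_body <- .positions_in(calls$position, win$body)
  in_up <- .positions_in(calls$position, win$upstream)
  join <- function(ix) if (length(ix)) paste(genes$locus_tag[sort(ix)],
                                             collapse = ";") else ""
  body_tags <- vapply(in_body, join, character(1L))
  up_tags <- vapply(in_up, join, character(1L))
  category <- ifelse(body_tags != "", "gene_body",
                     ifelse(up_tags != "", "upstream500", "intergenic"))
  all_tags <- mapply(function(b, u) {
    ix <- sort(unique(c(b, u)))
    if (length(ix)) paste(genes$locus_tag[ix], collapse = ";") else ""
  }, in_body, in_up)
  out <- cbind(calls,
               data.frame(category = category,
                          locus_tags = unname(all_tags),
                          body_locus_tags = body_tags,
                          upstream_locus_tags = up_tags,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Fraction of calls inside gene bodies or upstream windows
#'
#' @param assignments Output of [assign_sites()].
#' @return Percentage (0-100) of calls categorised `gene_body` or
#'   `upstream500`.
#' @export
fraction_in_gene_and_upstream <- function(assignments) {
  if (!nrow(assignments))
    stop("fraction undefined for an empty assignment set")
  100 * mean(assignments$category != "intergenic")
}

#' Percentage of genes carrying at least one methylation
#'
#' Reports both conventions side by side: genes hit in body or upstream
#' window, and genes hit in the body only.
#'
#' @param assignments Output of [assign_sites()].
#' @param genes Gene table.
#' @return List with `body_or_upstream` and `body_only` percentages.
#' @export
percent_genes_methylated <- function(assignments, genes) {
  if (!nrow(genes)) stop("gene table is empty")
  split_tags <- function(x) unique(unlist(strsplit(x[x != ""], ";",
                                                   fixed = TRUE)))
  body <- split_tags(assignments$body_locus_tags)
  up <- split_tags(assignments$upstream_locus_tags)
  list(
    body_or_upstream = 100 * length(unique(c(body, up))) / nrow(genes),
    body_only = 100 * length(body) / nrow(genes)
  )
}

#' Fraction of motif instances whose modified base carries a call
#'
#' @param hits Motif hit table from [scan_motif()].
#' @param calls Call table from [call_modifications()].
#' @return List with `pooled` fraction in `[0, 1]`, `per_motif` (named by
#'   pattern), `n_hits` and `n_methylated`.
#' @export
motif_methylation_fraction <- function(hits, calls) {
  if (!nrow(hits))
    return(list(pooled = NA_real_, per_motif = numeric(0),
                n_hits = 0L, n_methylated = 0L))
  call_keys <- paste(calls$position, calls$strand)
  meth <- paste(hits$meth_pos, hits$meth_strand) %in% call_keys
  per <- tapply(meth, paste0(hits$pattern, "/", hits$strand), mean)
  list(pooled = mean(meth),
       per_motif = per,
       n_hits = nrow(hits),
       n_methylated = sum(meth))
}

#' Strand balance of modification calls
#'
#' @param calls Call table.
#' @return Data frame per mod_type with `n_plus`, `n_minus`, `ratio`
#'   (plus/minus; `Inf` when only plus-strand calls exist) and `defined`
#'   (`FALSE` when the minus count is zero).
#' @export
strand_balance <- function(calls) {
  out <- lapply(c("m6A", "m4C"), function(m) {
    np <- sum(calls$mod_type == m & calls$strand == "+")
    nm <- sum(calls$mod_type == m & calls$strand == "-")
    data.frame(mod_type = m, n_plus = np, n_minus = nm,
               ratio = if (nm > 0) np / nm
                       else if (np > 0) Inf else NA_real_,
               defined = nm > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene methylation counts by modification type and region
#'
#' @param calls Call table.
#' @param genes Gene table.
#' @param genome A `genome_seq`.
#' @param upstream_len Upstream window length in bp.
#' @return Data frame with one row per gene: `locus_tag`, `n_m6A_body`,
#'   `n_m4C_body`, `n_m6A_upstream`, `n_m4C_upstream`.
#' @export
gene_methylation_profile <- function(calls, genes, genome,
                                     upstream_len = 500L) {
  win <- .gene_windows(genes, genome, upstream_len)
  in_body <- .positions_in(calls$position, win$body)
  in_up <- .positions_in(calls$position, win$upstream)
  n <- nrow(genes)
  cnt <- matrix(0L, nrow = n, ncol = 4L,
                dimnames = list(NULL, c("n_m6A_body", "n_m4C_body",
                                        "n_m6A_upstream", "n_m4C_upstream")))
  for (i in seq_len(nrow(calls))) {
    col_off <- if (calls$mod_type[i] == "m6A") 1L else 2L
    for (g in in_body[[i]]) cnt[g, col_off] <- cnt[g, col_off] + 1L
    for (g in in_up[[i]]) cnt[g, col_off + 2L] <- cnt[g, col_off + 2L] + 1L
  }
  cbind(data.frame(locus_tag = genes$locus_tag, stringsAsFactors = FALSE),
        as.data.frame(cnt))
}

#' Write feature assignments as TSV
#'
#' @param assignments Output of [assign_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  cols <- c("position", "strand", "mod_type", "category", "locus_tags")
  write.table(assignments[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
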