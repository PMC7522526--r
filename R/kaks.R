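## NG86-class counting estimation of Ka/Ks on pairwise codon alignments,
## with Jukes-Cantor multiple-hit correction, a Fisher exact significance
## test, the pair-exclusion filters, and the purifying-selection screen.

.BASES <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-base mutations that are synonymous, with mutations to stop codons
#' excluded from the denominator; the three fractions sum to the codon's
#' synonymous site count S and `N = 3 - S`.
#'
#' @param codon A sense codon over `{A,C,G,T}`.
#' @param code Genetic code as a named character vector mapping codons to
#'   amino acids (stop = `"*"`); default the standard code, which for
#'   codon-to-amino-acid assignments coincides with the bacterial table 11.
#' @return Named numeric `c(S = ..., N = ...)`.
#' @export
count_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  aa <- code[[codon]]
  if (is.null(aa) || is.na(aa)) stop(sprintf("invalid codon '%s'", codon))
  if (aa == "*") stop("stop codons carry no site counts")
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0L; valid <- 0L
    for (b in setdiff(.BASES, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      ma <- code[[mut]]
      if (ma == "*") next
      valid <- valid + 1L
      if (ma == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(S = s, N = 3 - s)
}

## Site-count lookup over all sense codons (built once per code).
.site_table <- function(code) {
  sense <- names(code)[code != "*"]
  t(vapply(sense, count_sites, numeric(2L), code = code))
}

## Average synonymous/nonsynonymous difference counts over minimal
## mutational pathways between two sense codons.  Pathways passing through
## an intermediate stop codon are excluded; if every pathway does, all
## pathways are used (stop-to-sense steps counted nonsynonymous).
.path_diffs <- function(c1, c2, code) {
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(d)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- switch(k,
                   `1` = list(d),
                   `2` = list(d, rev(d)),
                   `3` = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                                function(p) d[p]))
  paths <- lapply(orders, function(ord) {
    cur <- c1; sd <- 0L; nd <- 0L; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*" && nxt != c2) valid <- FALSE
      if (code[[nxt]] != "*" && code[[cur]] != "*" &&
          code[[nxt]] == code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid)
  })
  use <- Filter(function(p) p$valid, paths)
  if (!length(use)) use <- paths
  c(sd = mean(vapply(use, `[[`, numeric(1L), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1L), "nd")))
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), pmin(seq(3L, n + 2L, by = 3L), n))
}

#' Pairwise Ka/Ks by the counting method
#'
#' Nei-Gojobori-style estimation: fractional site counting per codon
#' (averaged over the two sequences), equal-weight pathway-averaged
#' difference counting for multi-difference codons, Jukes-Cantor correction
#' `K = -(3/4) ln(1 - (4/3) p)`, and a two-tailed Fisher exact test of
#' Ka != Ks on the rounded 2x2 table of synonymous/nonsynonymous differences
#' versus remaining sites.  Codon columns containing a gap or N are excluded
#' pairwise; stop codons are excluded and flagged when internal.
#'
#' @param aln A codon alignment: list with `seqA`, `seqB` (equal-length
#'   aligned coding sequences, ungapped length a multiple of 3) and
#'   optionally `id_pair`.
#' @param code Genetic code (see [count_sites()]).
#' @return One-row data frame with `id`, `n_codons`, `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ka`, `Ks`, `ka_ks`, `p_value`, `ratio_defined`,
#'   `saturated` and `internal_stop`.
#' @export
kaks_pair <- function(aln, code = Biostrings::GENETIC_CODE) {
  a <- toupper(aln$seqA); b <- toupper(aln$seqB)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("aligned length must be a multiple of 3")
  id <- if (!is.null(aln$id_pair)) paste(aln$id_pair, collapse = "|") else ""
  ca <- .split_codons(a); cb <- .split_codons(b)
  clean <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[clean]; cb <- cb[clean]
  is_stop <- code[ca] == "*" | code[cb] == "*"
  internal_stop <- length(is_stop) > 1L && any(is_stop[-length(is_stop)])
  ca <- ca[!is_stop]; cb <- cb[!is_stop]
  n_codons <- length(ca)
  if (!n_codons) stop("no analyzable codons in alignment")

  st <- .site_table(code)
  S <- (sum(st[ca, "S"]) + sum(st[cb, "S"])) / 2
  N <- (sum(st[ca, "N"]) + sum(st[cb, "N"])) / 2

  diff <- which(ca != cb)
  sd_nd <- vapply(diff, function(i) .path_diffs(ca[i], cb[i], code),
                  numeric(2L))
  Sd <- if (length(diff)) sum(sd_nd["sd", ]) else 0
  Nd <- if (length(diff)) sum(sd_nd["nd", ]) else 0

  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(ps); Ka <- jc(pn)
  saturated <- is.na(Ks) || is.na(Ka)
  ratio_defined <- !saturated && Ks > 0
  ka_ks <- if (ratio_defined) Ka / Ks else NA_real_

  tab <- round(matrix(c(Sd, S - Sd, Nd, N - Nd), nrow = 2L))
  tab[tab < 0L] <- 0L
  p_value <- if (Sd + Nd == 0) 1 else fisher.test(tab)$p.value

  data.frame(id = id, n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
             ps = ps, pn = pn, Ka = Ka, Ks = Ks, ka_ks = ka_ks,
             p_value = p_value, ratio_defined = ratio_defined,
             saturated = saturated, internal_stop = internal_stop,
             stringsAsFactors = FALSE)
}

#' Apply the pair-exclusion filters
#'
#' The published screen removed gene pairs with fewer than three
#' substitutions and Ka/Ks values with p-values above 0.05.  The default
#' removes a pair failing either criterion (remove-if-either reading); pass
#' `rule = "and"` for strict both-criteria removal.  Removed pairs carry
#' reason tags.
#'
#' @param results Row-bound [kaks_pair()] results.
#' @param min_substitutions Minimum rounded `Sd + Nd` (default 3).
#' @param max_p Maximum Fisher p-value (default 0.05).
#' @param rule `"either"` (default) or `"and"`.
#' @return `results` with added `retained` (logical) and `reason`
#'   (comma-joined tags, empty when retained) columns.
#' @export
filter_pairs <- function(results, min_substitutions = 3, max_p = 0.05,
                         rule = c("either", "and")) {
  rule <- match.arg(rule)
  few <- round(results$Sd + results$Nd) < min_substitutions
  nonsig <- is.na(results$p_value) | results$p_value > max_p
  removed <- if (rule == "either") few | nonsig else few & nonsig
  reason <- character(nrow(results))
  tag <- function(cond, label) ifelse(cond, label, NA_character_)
  reason <- apply(cbind(tag(few, "too_few_substitutions"),
                        tag(nonsig, "nonsignificant")), 1L, function(r)
                          paste(r[!is.na(r)], collapse = ","))
  reason[!removed] <- ""
  results$retained <- !removed
  results$reason <- reason
  results
}

#' Purifying-selection screen over gene sets
#'
#' Estimates Ka/Ks for every ortholog pair of each gene, applies the pair
#' filters and summarises the retained ratios per gene as box-plot
#' statistics.  A gene whose retained ratios have median below 1 is flagged
#' purifying; genes with no retained pair are flagged `no_data`.
#'
#' @param gene_sets Named list; each element a list of codon alignments (see
#'   [kaks_pair()]).
#' @param code Genetic code.
#' @param ... Passed to [filter_pairs()].
#' @return Data frame per gene: `gene`, `n_pairs`, `n_retained`, `median`,
#'   `q1`, `q3`, `purifying`, `no_data`.
#' @export
selection_screen <- function(gene_sets, code = Biostrings::GENETIC_CODE,
                             ...) {
  rows <- lapply(names(gene_sets), function(g) {
    res <- do.call(rbind, lapply(gene_sets[[g]], kaks_pair, code = code))
    res <- filter_pairs(res, ...)
    ratios <- res$ka_ks[res$retained & res$ratio_defined]
    if (!length(ratios))
      return(data.frame(gene = g, n_pairs = nrow(res), n_retained = 0L,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        purifying = NA, no_data = TRUE,
                        stringsAsFactors = FALSE))
    q <- quantile(ratios, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(gene = g, n_pairs = nrow(res), n_retained = length(ratios),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               purifying = q[2L] < 1, no_data = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a pairwise codon alignment from FASTA
#'
#' The file holds two aligned records (gaps allowed).
#'
#' @param path FASTA path.
#' @return A codon alignment list (`id_pair`, `seqA`, `seqB`).
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("paired FASTA must hold two records")
  list(id_pair = names(ss)[1:2],
       seqA = toupper(as.character(ss[[1L]])),
       seqB = toupper(as.character(ss[[2L]])))
}

#' Write Ka/Ks results as TSV
#'
#' @param results Filtered results from [filter_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kaks_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
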