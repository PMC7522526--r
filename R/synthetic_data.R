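## Seeded generators producing every input the pipeline consumes, with
## machine-readable planted ground truth for recovery testing.
##
## The default desk-scale scenario (200-kb circular genome, 200 genes, 20
## planted bipartite motif sites, 3 replicates per condition) preserves the
## statistical structure of a small-bacterium three-treatment study: a
## control condition, a cold treatment with elevated adenine methylation and
## mostly-repressive methylation/expression co-occurrence, and a UV
## treatment with reduced methylation.

.derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483629L

#' Define a synthetic study scenario
#'
#' All generator parameters in one seeded, serialisable object.  The same
#' seed yields byte-identical outputs.
#'
#' @param seed Integer master seed.
#' @param genome_length Genome size in bp.
#' @param gc_content GC fraction of the background sequence.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_mean,gene_length_sd Gene length distribution (bp).
#' @param motif_pattern,motif_offset Planted bipartite IUPAC motif and the
#'   0-based offset of its methylated adenine.
#' @param n_motif_sites Number of planted motif instances.
#' @param conditions Condition labels; the first entries of the probability
#'   vectors below must be named by these.
#' @param control Control condition label.
#' @param motif_meth_prob Per condition, probability that a planted motif
#'   site is methylated.
#' @param gene_meth_prob Per condition, probability that a gene carries
#'   gene-associated background methylation (body or upstream).
#' @param n_intergenic_sites Per condition, expected number of methylated
#'   sites planted strictly outside gene bodies and upstream windows.
#' @param upstream_len Upstream window length used when planting (bp).
#' @param p_down_given_meth,p_up_given_meth Transcript co-occurrence:
#'   probability that a methylated gene is down-/up-regulated in a
#'   treatment.
#' @param p_down_unmeth,p_up_unmeth Background DE probabilities for
#'   unmethylated genes.
#' @param de_effect_mean,de_effect_sd Planted |log2 fold change| of DE genes.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance
#'   (log2).
#' @param noise_sd Replicate noise on the log2 scale.
#' @param n_replicates Replicates per condition.
#' @param proteome_attenuation Multiplier carrying transcript effects to the
#'   protein level.
#' @param proteome_noise_sd Extra protein-level log2 noise.
#' @param dropout_mid,dropout_slope Missing-not-at-random dropout:
#'   `P(missing) = plogis(slope * (mid - log2 intensity))`.
#' @param ipd_mu,ipd_sigma Lognormal (meanlog, sdlog) of control IPDs.
#' @param ipd_multiplier Case/control IPD multiplier at methylated sites.
#' @param ipd_noise_sd Multiplicative log-scale kinetic noise.
#' @param coverage_range Per-condition mean coverage drawn uniformly from
#'   this range (x).
#' @param kinetics_background_sites Unmethylated positions included per
#'   kinetics table.
#' @param omega_list dN/dS values for ortholog simulation.
#' @param branch_length Expected base-change proposals per codon.
#' @return A list of class `methylome_scenario`.
#' @export
methylome_scenario <- function(
    seed = 1L,
    genome_length = 200000L,
    gc_content = 0.45,
    n_genes = 200L,
    gene_length_mean = 400,
    gene_length_sd = 120,
    motif_pattern = "CTAYNNNNNNNNTRTC",
    motif_offset = 2L,
    n_motif_sites = 20L,
    conditions = c("T26", "T4", "UV"),
    control = "T26",
    motif_meth_prob = c(T26 = 0.97, T4 = 0.97, UV = 0.92),
    gene_meth_prob = c(T26 = 0.25, T4 = 0.21, UV = 0.16),
    n_intergenic_sites = c(T26 = 60, T4 = 50, UV = 35),
    upstream_len = 500L,
    p_down_given_meth = 0.62,
    p_up_given_meth = 0.17,
    p_down_unmeth = 0.04,
    p_up_unmeth = 0.08,
    de_effect_mean = 2,
    de_effect_sd = 0.5,
    baseline_log2_mean = 10,
    baseline_log2_sd = 1.5,
    noise_sd = 0.25,
    n_replicates = 3L,
    proteome_attenuation = 0.8,
    proteome_noise_sd = 0.35,
    dropout_mid = 7,
    dropout_slope = 1.2,
    ipd_mu = 0,
    ipd_sigma = 0.15,
    ipd_multiplier = 4,
    ipd_noise_sd = 0.1,
    coverage_range = c(54, 70),
    kinetics_background_sites = 5000L,
    omega_list = c(0.2, 1),
    branch_length = 0.3) {
  probs <- c(motif_meth_prob, gene_meth_prob, p_down_given_meth,
             p_up_given_meth, p_down_unmeth, p_up_unmeth)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!control %in% conditions) stop("control must be one of the conditions")
  if (!all(conditions %in% names(motif_meth_prob)) ||
      !all(conditions %in% names(gene_meth_prob)) ||
      !all(conditions %in% names(n_intergenic_sites)))
    stop("per-condition parameters must be named by the conditions")
  if (genome_length < 10 * gene_length_mean)
    stop("genome_length must be at least 10x the mean gene length")
  structure(as.list(environment())[names(formals(methylome_scenario))],
            class = "methylome_scenario")
}

#' Generate a synthetic genome with genes and planted motifs
#'
#' Background bases are i.i.d. at the stated GC content.  Motif instances
#' (concrete realisations of the degenerate pattern) are inserted at
#' non-overlapping random positions on random strands; non-overlapping genes
#' are then laid out sequentially with random intergenic gaps.
#'
#' @param scenario A [methylome_scenario()].
#' @return List with `genome` (a `genome_seq`), `genes` (gene table) and
#'   `motif_hits` (planted truth in [scan_motif()] layout).
#' @export
generate_genome <- function(scenario) {
  sc <- scenario
  set.seed(.derive_seed(sc$seed, 11L))
  L <- sc$genome_length
  p <- c(A = (1 - sc$gc_content) / 2, C = sc$gc_content / 2,
         G = sc$gc_content / 2, T = (1 - sc$gc_content) / 2)
  chars <- sample(names(p), L, replace = TRUE, prob = p)

  motif <- iupac_motif(sc$motif_pattern, sc$motif_offset)
  k <- motif$length
  pv <- strsplit(motif$pattern, "")[[1L]]
  taken <- integer(0)
  hits <- list()
  for (i in seq_len(sc$n_motif_sites)) {
    repeat {
      s0 <- sample.int(L - k, 1L) - 1L   # avoid wrap for planted instances
      if (!any(abs(s0 - taken) < k)) break
    }
    taken <- c(taken, s0)
    concrete <- vapply(pv, function(code) {
      opts <- strsplit(IUPAC_CODES[[code]], "")[[1L]]
      opts[sample.int(length(opts), 1L)]
    }, character(1L))
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") concrete else
      rev(chartr("ACGT", "TGCA", concrete))
    chars[(s0 + 1L):(s0 + k)] <- strsplit(paste(ins, collapse = ""), "")[[1L]]
    hits[[i]] <- data.frame(
      start = s0, end = s0 + k, strand = strand,
      meth_pos = if (strand == "+") s0 + motif$methylated_offset
                 else s0 + k - 1L - motif$methylated_offset,
      meth_strand = strand, pattern = motif$pattern,
      stringsAsFactors = FALSE)
  }
  motif_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               meth_pos = integer(0), meth_strand = character(0),
               pattern = character(0), stringsAsFactors = FALSE)
  motif_hits <- motif_hits[order(motif_hits$start), , drop = FALSE]
  rownames(motif_hits) <- NULL

  lens <- pmax(100L, as.integer(round(rnorm(sc$n_genes, sc$gene_length_mean,
                                            sc$gene_length_sd))))
  total <- sum(lens)
  if (total > 0.95 * L)
    stop("infeasible packing: genes exceed 95% of the genome")
  gaps <- rpois(sc$n_genes, (L - total) / sc$n_genes)
  layout <- function(gaps) cumsum(gaps + c(0L, lens[-sc$n_genes]))
  starts <- layout(gaps)
  if (max(starts + lens) > L) {        # squeeze if gap draws overshoot
    gaps <- as.integer(floor(gaps * (L - total) / sum(gaps)))
    starts <- layout(gaps)
  }
  genes <- gene_table(sprintf("SYN_%04d", seq_len(sc$n_genes)),
                      starts, starts + lens,
                      sample(c("+", "-"), sc$n_genes, replace = TRUE))
  list(genome = genome_sequence("SYNTH_1", paste(chars, collapse = ""),
                                circular = TRUE),
       genes = genes, motif_hits = motif_hits)
}

## Truth bookkeeping category of a position: independent inline interval
## arithmetic (not assign_sites), used only by the generator.
.truth_category <- function(pos, genes, L, upstream_len) {
  in_iv <- function(p, s, e) {
    s <- s %% L; e2 <- s + (e - s)
    (p >= s & p < pmin(e2, L)) | (e2 > L & p < e2 - L)
  }
  body <- any(in_iv(pos, genes$start, genes$end))
  if (body) return("gene_body")
  up_s <- ifelse(genes$strand == "+", genes$start - upstream_len, genes$end)
  if (any(in_iv(pos, up_s, up_s + upstream_len))) return("upstream500")
  "intergenic"
}

## Strand/base/mod_type of a methylatable site at forward-frame position.
.site_record <- function(pos, fwd_base) {
  switch(fwd_base,
         A = list(strand = "+", base = "A", mod_type = "m6A"),
         T = list(strand = "-", base = "A", mod_type = "m6A"),
         C = list(strand = "+", base = "C", mod_type = "m4C"),
         G = list(strand = "-", base = "C", mod_type = "m4C"),
         NULL)
}

#' Plant per-condition methylation truth
#'
#' Motif sites are methylated with the per-condition motif probability;
#' genes carry background body/upstream sites with the per-condition gene
#' probability; intergenic sites are planted strictly outside gene bodies
#' and upstream windows.
#'
#' @param scenario A [methylome_scenario()].
#' @param genome,genes,motif_hits Output of [generate_genome()].
#' @return Named list (per condition) of truth data frames with columns
#'   `position`, `strand`, `base`, `mod_type`, `source`, `category` and
#'   `locus_tag` (empty for non-gene sites).
#' @export
generate_methylation <- function(scenario, genome, genes, motif_hits) {
  sc <- scenario
  L <- genome$length
  base_at <- function(p) substr(genome$seq, p + 1L, p + 1L)
  out <- list()
  for (ci in seq_along(sc$conditions)) {
    cond <- sc$conditions[ci]
    set.seed(.derive_seed(sc$seed, 100L + ci))
    rows <- list()
    ## motif-anchored m6A sites
    on <- runif(nrow(motif_hits)) < sc$motif_meth_prob[[cond]]
    for (i in which(on)) {
      pos <- motif_hits$meth_pos[i]
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, strand = motif_hits$meth_strand[i], base = "A",
        mod_type = "m6A", source = "motif",
        category = .truth_category(pos, genes, L, sc$upstream_len),
        locus_tag = "", stringsAsFactors = FALSE)
    }
    ## gene-associated background sites
    gene_on <- runif(nrow(genes)) < sc$gene_meth_prob[[cond]]
    for (g in which(gene_on)) {
      n_sites <- 1L + rpois(1L, 0.5)
      for (s in seq_len(n_sites)) {
        in_body <- runif(1L) > 0.3
        if (in_body) {
          pos <- (genes$start[g] +
                    sample.int(genes$end[g] - genes$start[g], 1L) - 1L) %% L
          cat_lab <- "gene_body"
        } else {
          up_s <- if (genes$strand[g] == "+")
            genes$start[g] - sc$upstream_len else genes$end[g]
          pos <- (up_s + sample.int(sc$upstream_len, 1L) - 1L) %% L
          cat_lab <- .truth_category(pos, genes, L, sc$upstream_len)
        }
        rec <- .site_record(pos, base_at(pos))
        if (is.null(rec)) next
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos, strand = rec$strand, base = rec$base,
          mod_type = rec$mod_type, source = "gene", category = cat_lab,
          locus_tag = genes$locus_tag[g], stringsAsFactors = FALSE)
      }
    }
    ## strictly intergenic sites
    n_int <- rpois(1L, sc$n_intergenic_sites[[cond]])
    placed <- 0L; tries <- 0L
    while (placed < n_int && tries < 50L * n_int + 1000L) {
      tries <- tries + 1L
      pos <- sample.int(L, 1L) - 1L
      if (.truth_category(pos, genes, L, sc$upstream_len) != "intergenic")
        next
      rec <- .site_record(pos, base_at(pos))
      if (is.null(rec)) next
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, strand = rec$strand, base = rec$base,
        mod_type = rec$mod_type, source = "intergenic",
        category = "intergenic", locus_tag = "", stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
    truth <- do.call(rbind, rows)
    truth <- truth[!duplicated(paste(truth$position, truth$strand)), ,
                   drop = FALSE]
    truth <- truth[order(truth$position, truth$strand), , drop = FALSE]
    rownames(truth) <- NULL
    out[[cond]] <- truth
  }
  out
}

#' Generate per-condition kinetics tables
#'
#' Control IPDs are lognormal; case IPDs equal the control times the
#' methylation multiplier at planted positions (times 1 elsewhere) with
#' multiplicative log-scale noise.  Coverage is Poisson around a
#' per-condition mean drawn from the scenario's coverage range.  Each table
#' holds all truth positions plus a seeded sample of unmethylated
#' background positions.
#'
#' @param scenario A [methylome_scenario()].
#' @param genome A `genome_seq` from [generate_genome()].
#' @param truth Output of [generate_methylation()].
#' @return Named list (per condition) of kinetics data frames.
#' @export
generate_kinetics <- function(scenario, genome, truth) {
  sc <- scenario
  L <- genome$length
  base_at <- function(p) substr(genome$seq, p + 1L, p + 1L)
  out <- list()
  for (ci in seq_along(sc$conditions)) {
    cond <- sc$conditions[ci]
    set.seed(.derive_seed(sc$seed, 200L + ci))
    tr <- truth[[cond]]
    truth_keys <- paste(tr$position, tr$strand)
    n_bg <- sc$kinetics_background_sites
    bg_pos <- sample.int(L, n_bg, replace = TRUE) - 1L
    bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    keep <- !paste(bg_pos, bg_strand) %in% truth_keys &
      !duplicated(paste(bg_pos, bg_strand))
    bg_pos <- bg_pos[keep]; bg_strand <- bg_strand[keep]
    fwd <- vapply(bg_pos, base_at, character(1L))
    bg_base <- ifelse(bg_strand == "+", fwd, chartr("ACGTN", "TGCAN", fwd))
    ok <- bg_base != "N"
    pos <- c(tr$position, bg_pos[ok])
    strand <- c(tr$strand, bg_strand[ok])
    base <- c(tr$base, bg_base[ok])
    meth <- c(rep(TRUE, nrow(tr)), rep(FALSE, sum(ok)))
    n <- length(pos)
    cov_mean <- runif(1L, sc$coverage_range[1L], sc$coverage_range[2L])
    ipd_control <- rlnorm(n, sc$ipd_mu, sc$ipd_sigma)
    mult <- ifelse(meth, sc$ipd_multiplier, 1)
    ipd_case <- ipd_control * mult * exp(rnorm(n, 0, sc$ipd_noise_sd))
    d <- data.frame(position = pos, strand = strand, base = base,
                    coverage = rpois(n, cov_mean),
                    ipd_case = ipd_case, ipd_control = ipd_control,
                    stringsAsFactors = FALSE)
    d <- d[order(d$position, d$strand), , drop = FALSE]
    rownames(d) <- NULL
    out[[cond]] <- d
  }
  out
}

#' Generate a replicated transcript expression matrix with planted DE
#'
#' Control-condition abundances are log-normal around per-gene baselines;
#' in each treatment a gene's DE status is sampled conditional on its
#' planted methylation state (body or upstream, any modification type), with
#' effect sizes from the scenario's log2-fold-change distribution.
#'
#' @param scenario A [methylome_scenario()].
#' @param genes Gene table.
#' @param truth Output of [generate_methylation()].
#' @return List with `matrix` (raw intensities, genes x condition_replicate
#'   samples) and `truth` (per gene and treatment: `methylated`, `status` in
#'   up/down/none, `true_log2fc`).
#' @export
generate_expression <- function(scenario, genes, truth) {
  sc <- scenario
  set.seed(.derive_seed(sc$seed, 300L))
  n <- nrow(genes)
  baseline <- rnorm(n, sc$baseline_log2_mean, sc$baseline_log2_sd)
  treatments <- setdiff(sc$conditions, sc$control)

  ## positional bookkeeping: a gene counts as methylated when any planted
  ## site (whatever its source) lies in its body or fixed upstream window
  L <- sc$genome_length
  up_s <- ifelse(genes$strand == "+", genes$start - sc$upstream_len,
                 genes$end)
  genes_with_sites <- function(pos) {
    hit <- logical(n)
    for (p in pos) {
      hit <- hit | (p >= genes$start & p < genes$end) |
        (((p - up_s) %% L) < sc$upstream_len)
    }
    genes$locus_tag[hit]
  }
  meth_genes <- lapply(truth, function(tr) genes_with_sites(tr$position))

  cols <- list()
  for (r in seq_len(sc$n_replicates))
    cols[[paste0(sc$control, "_", r)]] <-
      baseline + rnorm(n, 0, sc$noise_sd)

  truth_rows <- list()
  for (trt in treatments) {
    methylated <- genes$locus_tag %in% meth_genes[[trt]]
    u <- runif(n)
    p_down <- ifelse(methylated, sc$p_down_given_meth, sc$p_down_unmeth)
    p_up <- ifelse(methylated, sc$p_up_given_meth, sc$p_up_unmeth)
    status <- ifelse(u < p_down, "down",
                     ifelse(u < p_down + p_up, "up", "none"))
    effect <- abs(rnorm(n, sc$de_effect_mean, sc$de_effect_sd))
    lfc <- ifelse(status == "down", -effect,
                  ifelse(status == "up", effect, 0))
    for (r in seq_len(sc$n_replicates))
      cols[[paste0(trt, "_", r)]] <- baseline + lfc + rnorm(n, 0, sc$noise_sd)
    truth_rows[[trt]] <- data.frame(
      locus_tag = genes$locus_tag, condition = trt, methylated = methylated,
      status = status, true_log2fc = lfc, stringsAsFactors = FALSE)
  }
  log2mat <- do.call(cbind, cols)
  rownames(log2mat) <- genes$locus_tag
  list(matrix = 2^log2mat, truth = do.call(rbind, truth_rows))
}

#' Generate a proteome intensity matrix with MNAR dropout
#'
#' Protein log2 abundance follows the transcript baseline with the planted
#' effects attenuated by a stated factor plus extra noise; the probability
#' that a measurement is missing increases as intensity decreases
#' (logistic in log2 intensity).
#'
#' @param scenario A [methylome_scenario()].
#' @param expression Output of [generate_expression()].
#' @return List with `matrix` (raw intensities with `NA` dropout) and
#'   `truth` (per gene and treatment: `true_log2fc` at the protein level).
#' @export
generate_proteome <- function(scenario, expression) {
  sc <- scenario
  set.seed(.derive_seed(sc$seed, 400L))
  log2t <- log2(expression$matrix)
  cond <- condition_of(colnames(log2t))
  genes <- rownames(log2t)
  n <- length(genes)
  baseline <- rowMeans(log2t[, cond == sc$control, drop = FALSE])

  cols <- list()
  truth_rows <- list()
  for (cc in unique(cond)) {
    lfc_t <- if (cc == sc$control) rep(0, n) else {
      tt <- expression$truth[expression$truth$condition == cc, , drop = FALSE]
      tt$true_log2fc[match(genes, tt$locus_tag)]
    }
    lfc_p <- sc$proteome_attenuation * lfc_t
    for (r in seq_len(sc$n_replicates))
      cols[[paste0(cc, "_", r)]] <-
        baseline + lfc_p + rnorm(n, 0, sc$proteome_noise_sd)
    if (cc != sc$control)
      truth_rows[[cc]] <- data.frame(locus_tag = genes, condition = cc,
                                     true_log2fc = lfc_p,
                                     stringsAsFactors = FALSE)
  }
  log2p <- do.call(cbind, cols)
  rownames(log2p) <- genes
  miss <- matrix(runif(length(log2p)) <
                   plogis(sc$dropout_slope * (sc$dropout_mid - log2p)),
                 nrow = n)
  m <- 2^log2p
  m[miss] <- NA_real_
  list(matrix = m, truth = do.call(rbind, truth_rows))
}

#' Simulate one ortholog codon-alignment pair at a given omega
#'
#' Evolves a derived sequence from a random sense-codon ancestor by
#' single-base proposals (Poisson number, rate `branch_length` per codon):
#' proposals creating stop codons are rejected, synonymous proposals are
#' always accepted, and nonsynonymous proposals are accepted with
#' probability `omega`.  This acceptance-rejection scheme discriminates
#' omega regimes without full codon-model matrix exponentiation.
#'
#' @param cds_length Number of codons (>= 100).
#' @param omega dN/dS acceptance probability for nonsynonymous changes.
#' @param branch_length Expected proposals per codon.
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return List with `alignment` (a codon alignment for [kaks_pair()]) and
#'   realised `true_syn`/`true_nonsyn` accepted-substitution counts.
#' @export
generate_ortholog_pair <- function(cds_length, omega, branch_length, seed,
                                   code = Biostrings::GENETIC_CODE) {
  if (cds_length < 100L) stop("cds_length must be at least 100 codons")
  if (omega < 0) stop("omega must be nonnegative")
  set.seed(.derive_seed(seed, 0L))
  sense <- names(code)[code != "*"]
  anc <- sample(sense, cds_length, replace = TRUE)
  der <- anc
  true_syn <- 0L; true_nonsyn <- 0L
  n_prop <- rpois(1L, branch_length * cds_length)
  for (e in seq_len(n_prop)) {
    i <- sample.int(cds_length, 1L)
    pos <- sample.int(3L, 1L)
    cur <- der[i]
    ## propose uniformly among the position's viable (non-stop) mutants, so
    ## each codon position carries equal proposal weight regardless of how
    ## many of its mutations would create stops
    muts <- vapply(setdiff(.BASES, substr(cur, pos, pos)), function(b) {
      m <- cur; substr(m, pos, pos) <- b; m
    }, character(1L))
    muts <- muts[code[muts] != "*"]
    if (!length(muts)) next
    mut <- muts[sample.int(length(muts), 1L)]
    if (code[[mut]] == code[[cur]]) {
      der[i] <- mut; true_syn <- true_syn + 1L
    } else if (runif(1L) < omega) {
      der[i] <- mut; true_nonsyn <- true_nonsyn + 1L
    }
  }
  list(alignment = list(id_pair = c("ancestor", "derived"),
                        seqA = paste(anc, collapse = ""),
                        seqB = paste(der, collapse = "")),
       true_syn = true_syn, true_nonsyn = true_nonsyn)
}

#' Serialize a scenario to a flat key-value config file
#'
#' @param scenario A [methylome_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  fmt1 <- function(x) if (is.character(x)) x else
    format(x, digits = 17, trim = TRUE, scientific = FALSE)
  fmt <- function(v) {
    if (!is.null(names(v)) && length(names(v)) == length(v) &&
        all(names(v) != ""))
      paste(sprintf("%s:%s", names(v), fmt1(unname(v))), collapse = ",")
    else paste(fmt1(v), collapse = ",")
  }
  lines <- vapply(names(scenario), function(k)
    sprintf("%s=%s", k, fmt(scenario[[k]])), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario back from a config file
#'
#' @param path Config file written by [write_scenario()].
#' @return A `methylome_scenario` identical to the one written.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(lapply(kv, function(x)
    paste(x[-1L], collapse = "=")), vapply(kv, `[[`, character(1L), 1L))
  defaults <- formals(methylome_scenario)
  args <- list()
  for (k in names(vals)) {
    raw <- strsplit(vals[[k]], ",", fixed = TRUE)[[1L]]
    if (all(grepl(":", raw, fixed = TRUE))) {
      parts <- strsplit(raw, ":", fixed = TRUE)
      v <- setNames(as.numeric(vapply(parts, `[[`, character(1L), 2L)),
                    vapply(parts, `[[`, character(1L), 1L))
    } else {
      v <- type.convert(raw, as.is = TRUE)
    }
    default <- eval(defaults[[k]])
    if (is.integer(default)) v <- as.integer(v)
    if (is.character(default)) v <- as.character(v)
    args[[k]] <- v
  }
  do.call(methylome_scenario, args)
}

#' Write every synthetic input the pipeline reads
#'
#' Materialises a scenario: genome FASTA, annotation TSV, per-condition
#' kinetics TSVs, transcript and proteome matrices, ortholog pair FASTAs
#' with a manifest, the scenario config, and the planted truth as JSON.
#'
#' @param scenario A [methylome_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths plus the in-memory truth objects,
#'   invisibly.
#' @export
write_synthetic_inputs <- function(scenario, dir) {
  sc <- scenario
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_genome(sc)
  truth <- generate_methylation(sc, g$genome, g$genes, g$motif_hits)
  kin <- generate_kinetics(sc, g$genome, truth)
  expr <- generate_expression(sc, g$genes, truth)
  prot <- generate_proteome(sc, expr)

  paths <- list(genome = file.path(dir, "genome.fasta"),
                annotation = file.path(dir, "genes.tsv"),
                transcript = file.path(dir, "transcript.tsv"),
                proteome = file.path(dir, "proteome.tsv"),
                scenario = file.path(dir, "scenario.cfg"),
                truth = file.path(dir, "truth.json"))
  write_fasta(g$genome, paths$genome)
  write_annotation_tsv(g$genes, paths$annotation)
  write_expression(round(expr$matrix, 4), paths$transcript)
  write_expression(round(prot$matrix, 4), paths$proteome)
  write_scenario(sc, paths$scenario)
  for (cond in sc$conditions) {
    p <- file.path(dir, sprintf("kinetics_%s.tsv", cond))
    k <- kin[[cond]]
    k$ipd_case <- round(k$ipd_case, 6)
    k$ipd_control <- round(k$ipd_control, 6)
    write.table(k, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("kinetics_", cond)]] <- p
  }
  manifest <- file.path(dir, "ortholog_manifest.tsv")
  rows <- character(0)
  for (i in seq_along(sc$omega_list)) {
    pair <- generate_ortholog_pair(1000L, sc$omega_list[i], sc$branch_length,
                                   .derive_seed(sc$seed, 500L + i))
    fp <- file.path(dir, sprintf("ortholog_pair_%d.fasta", i))
    ss <- Biostrings::DNAStringSet(c(pair$alignment$seqA,
                                     pair$alignment$seqB))
    names(ss) <- pair$alignment$id_pair
    Biostrings::writeXStringSet(ss, fp, width = 70L)
    rows <- c(rows, sprintf("omega_%g\t%s", sc$omega_list[i], fp))
  }
  writeLines(c("gene\tpath", rows), manifest)
  paths$ortholog_manifest <- manifest
  jsonlite::write_json(
    list(motif_hits = g$motif_hits, methylation = truth,
         expression = expr$truth, proteome = prot$truth),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(genome_obj = g$genome, genes = g$genes,
                          motif_hits = g$motif_hits, methylation = truth,
                          expression_truth = expr$truth,
                          proteome_truth = prot$truth)))
}
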