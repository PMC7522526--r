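# Shared fixtures: small seeded scenarios and independent brute-force
# oracles kept deliberately separate from the package implementation.

tiny_scenario <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    genome_length = 50000L,
    n_genes = 60L,
    gene_length_mean = 300,
    gene_length_sd = 80,
    n_motif_sites = 10L,
    n_intergenic_sites = c(T26 = 20, T4 = 16, UV = 12),
    kinetics_background_sites = 1000L
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(methylome_scenario, args)
}

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent IUPAC matcher: own code table, simple window loop.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

brute_iupac_starts <- function(seq_str, pattern, circular = FALSE) {
  k <- nchar(pattern)
  L <- nchar(seq_str)
  ext <- if (circular) paste0(seq_str, substr(seq_str, 1, k - 1)) else seq_str
  pv <- strsplit(pattern, "")[[1]]
  ev <- strsplit(ext, "")[[1]]
  hits <- integer(0)
  last <- if (circular) L else L - k + 1
  for (s in seq_len(max(last, 0))) {
    w <- ev[s:(s + k - 1)]
    ok <- all(vapply(seq_len(k), function(i)
      w[i] %in% IUPAC_SETS[[pv[i]]], logical(1)))
    if (ok) hits <- c(hits, s - 1L)
  }
  hits
}

# Minimal trilevel record constructor for integrate tests.
make_records <- function(n, methylated, t_sig, t_lfc,
                         p_sig = rep(NA, n), p_lfc = rep(NA_real_, n),
                         m6A = methylated, m4C = rep(FALSE, n)) {
  structure(data.frame(
    locus_tag = sprintf("g%04d", seq_len(n)),
    n_m6A_body = as.integer(m6A), n_m4C_body = as.integer(m4C),
    n_m6A_upstream = 0L, n_m4C_upstream = 0L,
    m6A_methylated = m6A, m4C_methylated = m4C,
    methylated = methylated,
    transcript_log2fc = t_lfc, transcript_p = ifelse(t_sig, 0.01, 0.5),
    transcript_q = NA_real_, transcript_significant = t_sig,
    protein_log2fc = p_lfc, protein_p = NA_real_, protein_q = NA_real_,
    protein_significant = p_sig,
    stringsAsFactors = FALSE
  ), class = c("trilevel", "data.frame"))
}
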