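mk_calls <- function(position, strand = "+", mod_type = "m6A") {
  data.frame(position = as.integer(position),
             strand = rep_len(strand, length(position)),
             base = ifelse(rep_len(mod_type, length(position)) == "m6A", "A", "C"),
             mod_type = rep_len(mod_type, length(position)),
             ipd_ratio = rep_len(3, length(position)),
             coverage = rep_len(40L, length(position)),
             stringsAsFactors = FALSE)
}

test_that("assign_sites places calls in body, upstream window or intergenic space", {
  g <- genome_sequence("x", random_dna(3000, seed = 1))
  plus_gene <- gene_table("gp", 1000L, 2000L, "+")
  a <- assign_sites(mk_calls(c(1500, 700, 400, 2100)), plus_gene, g)
  expect_equal(a$category, c("gene_body", "upstream500", "intergenic",
                             "intergenic"))
  expect_equal(a$locus_tags, c("gp", "gp", "", ""))

  minus_gene <- gene_table("gm", 1000L, 2000L, "-")
  b <- assign_sites(mk_calls(c(2300, 700, 1999)), minus_gene, g)
  expect_equal(b$category, c("upstream500", "intergenic", "gene_body"))
})

test_that("minus-strand upstream agrees with a strand-reflection oracle", {
  # reflecting the genome maps a minus gene [s,e) to a plus gene [L-e, L-s)
  # and position p to L-1-p; the plus-strand upstream rule must then agree
  L <- 3000L
  g <- genome_sequence("x", random_dna(L, seed = 2))
  gref <- genome_sequence("x", reverse_complement_iupac(g$seq))
  minus_gene <- gene_table("g1", 1000L, 2000L, "-")
  plus_ref <- gene_table("g1", L - 2000L, L - 1000L, "+")
  for (pos in c(2300L, 2499L, 2500L, 1999L, 999L, 0L)) {
    direct <- assign_sites(mk_calls(pos), minus_gene, g)$category
    reflected <- assign_sites(mk_calls(L - 1L - pos), plus_ref, gref)$category
    expect_equal(direct, reflected, info = sprintf("position %d", pos))
  }
})

test_that("every call gets exactly one category and counts are complete", {
  sc <- tiny_scenario(seed = 3)
  gg <- generate_genome(sc)
  truth <- generate_methylation(sc, gg$genome, gg$genes, gg$motif_hits)
  calls <- mk_calls(truth$T26$position)
  calls$strand <- truth$T26$strand
  a <- assign_sites(calls, gg$genes, gg$genome)
  expect_equal(nrow(a), nrow(calls))
  expect_true(all(a$category %in% c("gene_body", "upstream500", "intergenic")))
  tab <- table(a$category)
  expect_equal(sum(tab), nrow(calls))
  expect_true(all((a$category == "intergenic") == (a$locus_tags == "")))
})

test_that("assignment is invariant under genome rotation", {
  sc <- tiny_scenario(seed = 4)
  gg <- generate_genome(sc)
  L <- gg$genome$length
  positions <- sort(sample(0:(L - 1L), 200))
  a0 <- assign_sites(mk_calls(positions), gg$genes, gg$genome)
  for (shift in c(137L, 25000L, 49999L)) {
    rot_seq <- paste0(substr(gg$genome$seq, shift + 1L, L),
                      substr(gg$genome$seq, 1L, shift))
    g_rot <- genome_sequence("x", rot_seq)
    genes_rot <- gg$genes
    genes_rot$start <- (genes_rot$start - shift) %% L
    genes_rot$end <- genes_rot$start + (gg$genes$end - gg$genes$start)
    a1 <- assign_sites(mk_calls((positions - shift) %% L), genes_rot, g_rot)
    expect_equal(a1$category, a0$category)
    expect_equal(a1$locus_tags, a0$locus_tags)
  }
})

test_that("assign_sites agrees with a brute-force membership test", {
  sc <- tiny_scenario(seed = 5, genome_length = 8000L, n_genes = 12L)
  gg <- generate_genome(sc)
  L <- gg$genome$length
  genes <- gg$genes
  positions <- 0:(L - 1L)
  a <- assign_sites(mk_calls(positions), genes, gg$genome)
  brute_cat <- vapply(positions, function(p) {
    in_body <- any(p >= genes$start & p < genes$end)
    up_s <- ifelse(genes$strand == "+", genes$start - 500L, genes$end)
    in_up <- any(((p - up_s) %% L) < 500L)
    if (in_body) "gene_body" else if (in_up) "upstream500" else "intergenic"
  }, character(1))
  expect_equal(a$category, brute_cat)
})

test_that("gene/upstream fraction and per-gene percentages are definitional", {
  g <- genome_sequence("x", random_dna(3000, seed = 6))
  genes <- gene_table(c("a", "b", "c"), c(600L, 1500L, 2400L),
                      c(900L, 1800L, 2700L), c("+", "+", "+"))
  # 49 calls in gene a's body, 51 intergenic (well before any upstream window)
  a <- assign_sites(mk_calls(c(600:648, rep(10, 51))), genes, g)
  expect_equal(fraction_in_gene_and_upstream(a), 49)
  pg <- percent_genes_methylated(a, genes)
  expect_equal(pg$body_or_upstream, 100 / 3, tolerance = 1e-12)
  expect_equal(pg$body_only, 100 / 3, tolerance = 1e-12)

  b <- assign_sites(mk_calls(c(700, 1600)), genes, g)
  expect_equal(percent_genes_methylated(b, genes)$body_or_upstream, 200 / 3,
               tolerance = 1e-12)
  empty <- assign_sites(mk_calls(integer(0)), genes, g)
  expect_error(fraction_in_gene_and_upstream(empty), "empty")
  expect_equal(percent_genes_methylated(empty, genes)$body_or_upstream, 0)
})

test_that("upstream windows are full fixed windows, not truncated by neighbours", {
  g <- genome_sequence("x", random_dna(3000, seed = 7))
  # gene b starts 100 bp after gene a ends; b's 500-bp window reaches into a
  genes <- gene_table(c("a", "b"), c(500L, 1100L), c(1000L, 1400L), c("+", "+"))
  a <- assign_sites(mk_calls(800L), genes, g)
  expect_equal(a$category, "gene_body")            # body of a wins
  expect_true(grepl("a", a$body_locus_tags) && grepl("b", a$upstream_locus_tags))
  expect_equal(sort(strsplit(a$locus_tags, ";")[[1]]), c("a", "b"))
})

test_that("motif methylation fraction counts called anchor positions", {
  hits <- data.frame(start = 0:99, end = 16L, strand = "+",
                     meth_pos = 0:99, meth_strand = "+",
                     pattern = "CTAYNNNNNNNNTRTC", stringsAsFactors = FALSE)
  expect_equal(motif_methylation_fraction(hits, mk_calls(integer(0)))$pooled, 0)
  expect_equal(motif_methylation_fraction(hits, mk_calls(0:99))$pooled, 1)
  f <- motif_methylation_fraction(hits, mk_calls(0:91))
  expect_equal(f$pooled, 0.92)
  expect_equal(f$n_methylated, 92L)
  # a call on the wrong strand does not methylate the anchor
  wrong <- mk_calls(0:91); wrong$strand <- "-"
  expect_equal(motif_methylation_fraction(hits, wrong)$pooled, 0)
})

test_that("strand balance reports counts, ratio and undefined flags", {
  calls <- rbind(mk_calls(1:10, "+"), mk_calls(11:20, "-"))
  sb <- strand_balance(calls)
  expect_equal(sb$ratio[sb$mod_type == "m6A"], 1)
  expect_false(sb$defined[sb$mod_type == "m4C"])
  expect_equal(sb$n_plus[sb$mod_type == "m4C"], 0)

  set.seed(8)
  strands <- ifelse(runif(2000) < 0.6, "+", "-")
  sb2 <- strand_balance(mk_calls(seq_len(2000), strands))
  # planted 0.6/0.4 gives ratio 1.5 within 3-sigma binomial error
  expect_gt(sb2$ratio[1], 1.28)
  expect_lt(sb2$ratio[1], 1.75)
})

test_that("gene methylation profiles count body and upstream sites per type", {
  g <- genome_sequence("x", random_dna(3000, seed = 9))
  genes <- gene_table(c("a", "b"), c(1000L, 2000L), c(1500L, 2500L), c("+", "-"))
  calls <- rbind(mk_calls(c(1100, 1200), "+", "m6A"),
                 mk_calls(1300, "+", "m4C"),
                 mk_calls(700, "+", "m6A"),     # upstream of a
                 mk_calls(2600, "+", "m4C"))    # upstream of b (minus strand)
  pr <- gene_methylation_profile(calls, genes, g)
  expect_equal(pr$n_m6A_body, c(2L, 0L))
  expect_equal(pr$n_m4C_body, c(1L, 0L))
  expect_equal(pr$n_m6A_upstream, c(1L, 0L))
  expect_equal(pr$n_m4C_upstream, c(0L, 1L))
})
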