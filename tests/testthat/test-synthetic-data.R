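test_that("fixed seeds give byte-identical outputs", {
  sc <- tiny_scenario(seed = 101)
  g1 <- generate_genome(sc)
  g2 <- generate_genome(sc)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$motif_hits, g2$motif_hits)

  t1 <- generate_methylation(sc, g1$genome, g1$genes, g1$motif_hits)
  t2 <- generate_methylation(sc, g2$genome, g2$genes, g2$motif_hits)
  expect_identical(t1, t2)
  expect_identical(generate_kinetics(sc, g1$genome, t1),
                   generate_kinetics(sc, g1$genome, t1))
  expect_identical(generate_expression(sc, g1$genes, t1),
                   generate_expression(sc, g1$genes, t1))

  # a different seed changes the genome
  expect_false(identical(
    generate_genome(tiny_scenario(seed = 102))$genome$seq, g1$genome$seq))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(tiny_scenario(gene_meth_prob = c(T26 = 1.2, T4 = 0.2, UV = 0.2)),
               "probabilities")
  expect_error(tiny_scenario(control = "T99"), "control")
  expect_error(methylome_scenario(genome_length = 1000L, n_genes = 5L,
                                  gene_length_mean = 400),
               "10x")
})

test_that("scenario config files round-trip exactly", {
  sc <- tiny_scenario(seed = 103, noise_sd = 0.31,
                      motif_meth_prob = c(T26 = 0.9, T4 = 0.95, UV = 0.85))
  f <- withr::local_tempfile(fileext = ".cfg")
  write_scenario(sc, f)
  back <- read_scenario(f)
  expect_equal(back, sc)
})

test_that("planted motifs are a recovered subset and zero density means chance rate", {
  sc <- tiny_scenario(seed = 104, n_motif_sites = 30L)
  g <- generate_genome(sc)
  expect_equal(nrow(g$motif_hits), 30L)
  hits <- scan_motif(g$genome, iupac_motif(sc$motif_pattern, sc$motif_offset),
                     "both")
  expect_gte(nrow(hits), 30L)
  expect_true(all(paste(g$motif_hits$start, g$motif_hits$strand) %in%
                    paste(hits$start, hits$strand)))
  # planted anchors are adenines on their own strand
  anchor <- substr(rep(g$genome$seq, nrow(g$motif_hits)),
                   g$motif_hits$meth_pos + 1, g$motif_hits$meth_pos + 1)
  expect_true(all(ifelse(g$motif_hits$meth_strand == "+", anchor == "A",
                         anchor == "T")))

  sc0 <- tiny_scenario(seed = 105, n_motif_sites = 0L)
  g0 <- generate_genome(sc0)
  expect_equal(nrow(g0$motif_hits), 0L)
  n0 <- nrow(scan_motif(g0$genome,
                        iupac_motif(sc0$motif_pattern, sc0$motif_offset),
                        "both"))
  p <- sc0$genome_length / 16384 * 2
  expect_lt(n0, p + 4 * sqrt(p) + 1)
})

test_that("kinetic separation drives recall: multiplier, noise and coverage", {
  sc <- tiny_scenario(seed = 106)
  g <- generate_genome(sc)
  truth <- generate_methylation(sc, g$genome, g$genes, g$motif_hits)
  kin <- generate_kinetics(sc, g$genome, truth)
  calls <- call_modifications(kin$T26, call_params())
  truth_keys <- paste(truth$T26$position, truth$T26$strand)
  call_keys <- paste(calls$position, calls$strand)
  expect_equal(mean(truth_keys %in% call_keys), 1)   # recall
  expect_equal(mean(call_keys %in% truth_keys), 1)   # precision

  # an unmethylated signal (multiplier 1) yields nothing but the noise tail
  sc1 <- tiny_scenario(seed = 107, ipd_multiplier = 1)
  t1 <- generate_methylation(sc1, g$genome, g$genes, g$motif_hits)
  k1 <- generate_kinetics(sc1, g$genome, t1)
  c1 <- call_modifications(k1$T26, call_params())
  expect_lt(nrow(c1), 3)

  # low coverage fails the strict >25x filter almost everywhere
  sc2 <- tiny_scenario(seed = 108, coverage_range = c(10, 10))
  k2 <- generate_kinetics(sc2, g$genome, truth)
  c2 <- call_modifications(k2$T26, call_params())
  expect_lt(nrow(c2), 0.01 * nrow(truth$T26) + 1)
})

test_that("methylation truth respects per-condition rates and categories", {
  sc <- tiny_scenario(seed = 109)
  g <- generate_genome(sc)
  truth <- generate_methylation(sc, g$genome, g$genes, g$motif_hits)
  expect_named(truth, c("T26", "T4", "UV"))
  for (cond in names(truth)) {
    tr <- truth[[cond]]
    expect_true(all(tr$category %in%
                      c("gene_body", "upstream500", "intergenic")))
    expect_true(all(tr$base %in% c("A", "C")))
    expect_false(any(duplicated(paste(tr$position, tr$strand))))
    # motif-anchored sites are all adenine
    expect_true(all(tr$mod_type[tr$source == "motif"] == "m6A"))
  }
  # UV plants fewer sites than the control in expectation
  expect_lt(nrow(truth$UV), nrow(truth$T26))
})

test_that("expression and proteome generators carry planted effects through", {
  sc <- tiny_scenario(seed = 110, noise_sd = 0,
                      proteome_attenuation = 1, proteome_noise_sd = 0,
                      dropout_mid = -100)
  g <- generate_genome(sc)
  truth <- generate_methylation(sc, g$genome, g$genes, g$motif_hits)
  expr <- generate_expression(sc, g$genes, truth)
  prot <- generate_proteome(sc, expr)
  expect_equal(sum(is.na(prot$matrix)), 0L)

  tde <- transcript_de(expr$matrix, "T4", "T26")
  pde <- proteome_de(proteome_preprocess(prot$matrix), "T4", "T26")
  expect_equal(pde$log2fc, tde$log2fc, tolerance = 1e-9)

  # dropout is intensity-dependent when enabled
  sc2 <- tiny_scenario(seed = 111, dropout_mid = 9, dropout_slope = 1.5)
  expr2 <- generate_expression(sc2, g$genes, truth)
  prot2 <- generate_proteome(sc2, expr2)
  expect_gt(mean(is.na(prot2$matrix)), 0.02)
  rm <- rowMeans(prot2$matrix, na.rm = TRUE)
  ok <- is.finite(rm)                     # all-missing rows have no mean
  lo <- ok & rm < median(rm[ok])
  hi <- ok & rm >= median(rm[ok])
  expect_gt(mean(is.na(prot2$matrix[lo, ])), mean(is.na(prot2$matrix[hi, ])))
})

test_that("ortholog simulation respects omega limits", {
  p0 <- generate_ortholog_pair(150L, 0, 0.5, seed = 112)
  expect_equal(p0$true_nonsyn, 0L)
  expect_equal(kaks_pair(p0$alignment)$Ka, 0)
  expect_error(generate_ortholog_pair(50L, 0.2, 0.3, seed = 1), "100")
  expect_error(generate_ortholog_pair(150L, -1, 0.3, seed = 1), "omega")
})

test_that("write_synthetic_inputs materialises every pipeline input", {
  dir <- withr::local_tempdir()
  sc <- tiny_scenario(seed = 113)
  paths <- write_synthetic_inputs(sc, dir)
  for (p in c("genome", "annotation", "transcript", "proteome", "scenario",
              "truth", "kinetics_T26", "kinetics_T4", "kinetics_UV",
              "ortholog_manifest"))
    expect_true(file.exists(paths[[p]]), info = p)
  g <- read_fasta(paths$genome)
  expect_equal(g$length, sc$genome_length)
  expect_equal(nrow(read_annotation(paths$annotation)), sc$n_genes)
  kin <- read_kinetics(paths$kinetics_T26)
  expect_true(all(c("ipd_case", "ipd_control") %in% names(kin)))
  tr <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_named(tr, c("motif_hits", "methylation", "expression", "proteome"))
})
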