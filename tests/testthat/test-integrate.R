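test_that("build_trilevel joins the three levels over the gene universe", {
  genes <- gene_table(c("g1", "g2", "g3"), c(0L, 1000L, 2000L),
                      c(500L, 1500L, 2500L), c("+", "+", "-"))
  profile <- data.frame(locus_tag = "g1", n_m6A_body = 2L, n_m4C_body = 0L,
                        n_m6A_upstream = 0L, n_m4C_upstream = 0L)
  tde <- data.frame(feature_id = c("g1", "g2", "g3"),
                    log2fc = c(-2, 0.1, 1), t_stat = 0, df = 4,
                    p_value = c(0.001, 0.9, 0.2), q_value = c(0.003, 0.9, 0.3),
                    tested = TRUE, significant = c(TRUE, FALSE, FALSE))
  pde <- tde; pde$log2fc <- c(-1.5, 0, 0)
  tri <- build_trilevel(profile, tde, pde, genes)
  expect_equal(nrow(tri), 3L)
  expect_equal(tri$methylated, c(TRUE, FALSE, FALSE))
  expect_true(tri$transcript_significant[1] && tri$protein_significant[1])
  expect_equal(tri$transcript_log2fc, c(-2, 0.1, 1))

  # empty inputs give an empty record list
  empty <- build_trilevel(profile[0, ], tde[0, ], NULL, genes[0, ])
  expect_equal(nrow(empty), 0L)

  # genes absent from an assay are absent (NA), not zero
  tri2 <- build_trilevel(profile, tde[1:2, ], NULL, genes)
  expect_true(is.na(tri2$transcript_p[3]))
  expect_true(all(is.na(tri2$protein_significant)))

  # stray DE features are excluded with a warning
  stray <- rbind(tde, data.frame(feature_id = "nope", log2fc = 1, t_stat = 0,
                                 df = 4, p_value = 0.01, q_value = 0.02,
                                 tested = TRUE, significant = TRUE))
  expect_warning(tri3 <- build_trilevel(profile, stray, NULL, genes),
                 "not in the gene universe")
  expect_equal(attr(tri3, "excluded"), "nope")
})

test_that("co-occurrence summary computes both denominators and tri-level traceability", {
  rec <- make_records(
    n = 10,
    methylated = c(rep(TRUE, 4), rep(FALSE, 6)),
    t_sig = c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5)),
    t_lfc = c(-2, -1, 0.5, 0, -3, rep(0, 5)),
    p_sig = c(TRUE, FALSE, rep(FALSE, 8)),
    p_lfc = c(-1, rep(0, 9)))
  s <- co_occurrence_summary(rec)
  expect_equal(s$pct_methylated_down_all_genes, 20)     # 2 of 10
  expect_equal(s$pct_methylated_up_all_genes, 10)       # 1 of 10
  expect_equal(s$pct_methylated_down_methylated_genes, 50)
  expect_equal(s$pct_trilevel, 10)                      # gene 1 only
  tr_m6A <- s$updown_fractions[s$updown_fractions$level == "transcript" &
                                 s$updown_fractions$mod_type == "m6A", ]
  expect_equal(tr_m6A$n, 3L)
  expect_equal(tr_m6A$down_fraction, 2 / 3)
  expect_equal(tr_m6A$up_fraction, 1 / 3)
})

test_that("up and down fractions sum to one in every defined cell group", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 200
    rec <- make_records(
      n = n,
      methylated = runif(n) < 0.4,
      t_sig = runif(n) < 0.3,
      t_lfc = rnorm(n),
      p_sig = runif(n) < 0.2,
      p_lfc = rnorm(n),
      m6A = runif(n) < 0.3,
      m4C = runif(n) < 0.2)
    rec$methylated <- rec$m6A_methylated | rec$m4C_methylated
    rec$methylated <- rec$methylated  # keep consistency with mod flags
    s <- co_occurrence_summary(rec)
    u <- s$updown_fractions
    def <- u[u$defined, ]
    expect_true(all(abs(def$up_fraction + def$down_fraction - 1) < 1e-12))
    # invariance to gene order
    s2 <- co_occurrence_summary(rec[sample(n), ])
    expect_equal(s2$pct_methylated_down_all_genes,
                 s$pct_methylated_down_all_genes)
    expect_equal(s2$updown_fractions$down_fraction, u$down_fraction)
  }
})

test_that("degenerate co-occurrence inputs yield flags, not 0/0", {
  # all methylated genes down-regulated
  rec <- make_records(5, methylated = rep(TRUE, 5), t_sig = rep(TRUE, 5),
                      t_lfc = rep(-1, 5))
  s <- co_occurrence_summary(rec)
  u <- s$updown_fractions
  expect_equal(u$down_fraction[u$level == "transcript" & u$mod_type == "m6A"], 1)

  # no DE genes at all: percentages 0, cell groups undefined
  rec0 <- make_records(5, methylated = rep(TRUE, 5), t_sig = rep(FALSE, 5),
                       t_lfc = rep(0, 5))
  s0 <- co_occurrence_summary(rec0)
  expect_equal(s0$pct_methylated_down_all_genes, 0)
  expect_true(all(!s0$updown_fractions$defined))
  expect_true(all(is.na(s0$updown_fractions$down_fraction)))
  expect_error(co_occurrence_summary(rec0[0, ]), "empty")
})

test_that("a planted P(down | methylated) of 0.78 is recovered within 3 sigma", {
  set.seed(17)
  n <- 500
  down <- runif(n) < 0.78
  rec <- make_records(n, methylated = rep(TRUE, n), t_sig = rep(TRUE, n),
                      t_lfc = ifelse(down, -1, 1))
  s <- co_occurrence_summary(rec)
  u <- s$updown_fractions
  est <- u$down_fraction[u$level == "transcript" & u$mod_type == "m6A"]
  expect_lt(abs(est - 0.78), 3 * sqrt(0.78 * 0.22 / n))
})

test_that("methylation deltas are signed relative changes with zero-control flags", {
  mk_sum <- function(n6, n4) structure(list(n_m6A = n6, n_m4C = n4),
                                       class = "methylome_summary")
  d <- methylation_deltas(mk_sum(50, 125), mk_sum(100, 100))
  expect_equal(d$rel_change[d$mod_type == "m6A"], -0.5)
  expect_equal(d$rel_change[d$mod_type == "m4C"], 0.25)
  d0 <- methylation_deltas(mk_sum(5, 5), mk_sum(0, 10))
  expect_false(d0$defined[d0$mod_type == "m6A"])
  expect_true(is.na(d0$rel_change[d0$mod_type == "m6A"]))
})

test_that("noise-free generator runs reproduce every planted summary exactly", {
  sc <- tiny_scenario(seed = 18, noise_sd = 0, proteome_noise_sd = 0,
                      dropout_mid = -100)
  gg <- generate_genome(sc)
  truth <- generate_methylation(sc, gg$genome, gg$genes, gg$motif_hits)
  kin <- generate_kinetics(sc, gg$genome, truth)
  expr <- generate_expression(sc, gg$genes, truth)
  prot <- generate_proteome(sc, expr)
  expect_equal(sum(is.na(prot$matrix)), 0L)

  calls <- call_modifications(kin$T4, call_params())
  expect_equal(paste(calls$position, calls$strand),
               paste(truth$T4$position, truth$T4$strand))
  a <- assign_sites(calls, gg$genes, gg$genome)
  expect_equal(fraction_in_gene_and_upstream(a),
               100 * mean(truth$T4$category != "intergenic"))

  tde <- transcript_de(expr$matrix, "T4", "T26")
  tt <- expr$truth[expr$truth$condition == "T4", ]
  expect_equal(tde$significant[match(tt$locus_tag, tde$feature_id)],
               tt$status != "none")
  expect_equal(tde$log2fc[match(tt$locus_tag, tde$feature_id)],
               tt$true_log2fc, tolerance = 1e-9)

  profile <- gene_methylation_profile(calls, gg$genes, gg$genome)
  pde <- proteome_de(proteome_preprocess(prot$matrix), "T4", "T26")
  tri <- build_trilevel(profile, tde, pde, gg$genes)
  s <- co_occurrence_summary(tri)
  planted_down <- mean(tt$methylated & tt$status == "down")
  expect_equal(s$pct_methylated_down_all_genes, 100 * planted_down,
               tolerance = 1e-9)
})
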