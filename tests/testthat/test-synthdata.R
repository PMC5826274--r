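test_that("identical configs give bit-identical output across all generators", {
  cfg <- small_synth(n_samples = 12, sizes = c(20, 15), background = 10, seed = 99)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_traits(a$truth, cfg), simulate_traits(b$truth, cfg))
  expect_identical(simulate_condition2(a$expr, a$truth, cfg),
                   simulate_condition2(b$expr, b$truth, cfg))
  len <- tibble::tibble(gene_id = a$expr$gene_id, length = 1000)
  expect_identical(simulate_counts(a$expr, len, seed = 5),
                   simulate_counts(b$expr, len, seed = 5))
  expect_identical(simulate_interactions(a$truth, seed = 5),
                   simulate_interactions(b$truth, seed = 5))
})

test_that("zero-noise, kME-1 module genes are exactly proportional to the eigengene", {
  cfg <- synth_config(n_samples = 10, module_sizes = 25, n_background_genes = 0,
                      kme_targets = 1, noise_sd = 0, seed = 3)
  sim <- simulate_expression(cfg)
  m <- as_expr_matrix(sim$expr)
  e <- sim$truth$eigengenes$turquoise
  cors <- apply(m, 1, stats::cor, y = e)
  expect_equal(unname(abs(cors)), rep(1, nrow(m)), tolerance = 1e-12)
})

test_that("realized module membership matches the kME target", {
  cfg <- synth_config(n_samples = 200, module_sizes = 150, n_background_genes = 0,
                      kme_targets = 0.8, seed = 17)
  sim <- simulate_expression(cfg)
  m <- as_expr_matrix(sim$expr)
  e <- sim$truth$eigengenes$turquoise
  mean_abs_cor <- mean(abs(apply(m, 1, stats::cor, y = e)))
  expect_lt(abs(mean_abs_cor - 0.8), 0.05)
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(module_sizes = integer(0)), "sum to a positive")
  expect_error(synth_config(n_samples = 3), "n_samples")
  expect_error(synth_config(kme_targets = 1.2), "kme_targets")
  expect_error(synth_config(preserved_modules = "nosuch"), "unknown module")
})

test_that("near-Poisson counts at deep coverage recover the target abundances", {
  set.seed(1)
  n <- 10000
  abund <- stats::rlnorm(n, 4, 1.5)
  abund[sample.int(n, 50)] <- 0
  m <- matrix(abund, ncol = 1, dimnames = list(sprintf("G%05d", 1:n), "s1"))
  expr <- as_expr_tibble(m)
  len <- tibble::tibble(gene_id = rownames(m),
                        length = round(stats::runif(n, 500, 4000)))
  counts <- simulate_counts(expr, len, library_sizes = 2e7, dispersion = 0,
                            seed = 4, log2_input = FALSE)
  expect_true(all(as_expr_matrix(counts)[abund == 0, 1] == 0))
  tpm <- counts_to_tpm(counts, len)
  nonzero <- abund > 0
  expect_gt(stats::cor(as_expr_matrix(tpm)[nonzero, 1], abund[nonzero]), 0.99)
})

test_that("count simulation validates gene lengths", {
  expr <- expr_fixture(matrix(1:4, 2))
  bad <- tibble::tibble(gene_id = expr$gene_id, length = c(1000, -5))
  expect_error(simulate_counts(expr, bad, seed = 1), "positive")
})

test_that("preserved modules re-occur in condition 2, scrambled ones do not", {
  cfg <- synth_config(n_samples = 100, module_sizes = c(60, 60),
                      n_background_genes = 120, kme_targets = 0.9,
                      noise_sd = 0.5, preserved_modules = "turquoise", seed = 8)
  sim <- simulate_expression(cfg)
  e2 <- simulate_condition2(sim$expr, sim$truth, cfg, n_samples = 100)
  m1 <- as_expr_matrix(sim$expr)
  m2 <- as_expr_matrix(e2)
  mods <- sim$truth$modules

  pres <- mods$gene_id[mods$module == "turquoise"]
  c1 <- stats::cor(t(m1[pres, ]))
  c2 <- stats::cor(t(m2[pres, ]))
  ut <- upper.tri(c1)
  expect_gt(stats::cor(c1[ut], c2[ut]), 0.5)

  # scrambled module: within-module |cor| indistinguishable from background
  scr <- mods$gene_id[mods$module == "blue"]
  bg <- mods$gene_id[mods$module == "grey"]
  cs <- stats::cor(t(m2[scr, ]))
  obs <- mean(abs(cs[upper.tri(cs)]))
  set.seed(42)
  null <- replicate(200, {
    g <- sample(bg, length(scr))
    cb <- stats::cor(t(m2[g, ]))
    mean(abs(cb[upper.tri(cb)]))
  })
  p <- mean(abs(null - mean(null)) >= abs(obs - mean(null)))
  expect_gt(p, 0.05)

  # marginal means are preserved under scrambling
  expect_equal(unname(rowMeans(m2[scr, ])), unname(sim$truth$gene_means[scr]),
               tolerance = 0.5)
})

test_that("condition-2 attenuation weakens but keeps coexpression, and labels are checked", {
  cfg <- synth_config(n_samples = 80, module_sizes = c(50, 50),
                      n_background_genes = 0, kme_targets = 0.9,
                      preserved_modules = c("turquoise", "blue"), seed = 2)
  sim <- simulate_expression(cfg)
  e2 <- simulate_condition2(sim$expr, sim$truth, cfg, attenuation = c(blue = 0.4))
  m2 <- as_expr_matrix(e2)
  mods <- sim$truth$modules
  mean_cor <- function(g) {
    cc <- stats::cor(t(m2[g, ]))
    mean(cc[upper.tri(cc)])
  }
  full <- mean_cor(mods$gene_id[mods$module == "turquoise"])
  att <- mean_cor(mods$gene_id[mods$module == "blue"])
  expect_gt(full, att)
  expect_gt(att, 0.05)
  cfg_bad <- cfg
  cfg_bad$preserved_modules <- "magenta"
  expect_error(simulate_condition2(sim$expr, sim$truth, cfg_bad), "unknown module")
})

test_that("annotations enrich their target modules and interactions partition at 0.9", {
  cfg <- small_synth(n_samples = 10, sizes = c(40, 30), background = 30, seed = 12)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotations(sim$truth, n_terms = 30, seed = 7)
  expect_equal(nrow(ann), 30)
  expect_true(all(ann$p_value >= 0 & ann$p_value <= 1))
  enriched <- ann[!is.na(ann$target_module), ]
  frac_in <- purrr::map2_dbl(enriched$genes, enriched$target_module, function(g, m) {
    mean(g %in% sim$truth$modules$gene_id[sim$truth$modules$module == m])
  })
  expect_true(all(frac_in >= 0.5))

  edges <- simulate_interactions(sim$truth, n_edges = 150, seed = 7)
  expect_equal(edges$high_confidence, edges$confidence >= 0.9)
  expect_true(all(edges$gene_i != edges$gene_j))
  expect_false(any(duplicated(paste(edges$gene_i, edges$gene_j))))
})

test_that("promoter simulation plants scorable motifs and respects motif_rate", {
  pwm <- read_jaspar(system.file("extdata", "synthetic_foxp2_like.jaspar",
                                 package = "songnet"))
  none <- simulate_promoters(pwm, n = 20, motif_rate = 0, seed = 3)
  expect_equal(nrow(none$planted), 0)
  some <- simulate_promoters(pwm, n = 50, motif_rate = 1, seed = 3)
  expect_equal(nrow(some$planted), 50)
  expect_true(all(nchar(some$sequences) == 1000))
  expect_true(all(some$planted$offset >= 0 &
                    some$planted$offset <= 1000 - ncol(pwm$weights)))
  # the planted substring really sits at the recorded offset
  w <- ncol(pwm$weights)
  extracted <- substr(some$sequences[some$planted$seq_id],
                      some$planted$offset + 1, some$planted$offset + w)
  expect_equal(unname(extracted), some$planted$motif)
  expect_error(simulate_promoters(pwm, n = 2, promoter_length = 5, seed = 1),
               "longer than promoter")
})
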