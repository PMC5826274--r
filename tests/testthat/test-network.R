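test_that("signed adjacency maps correlation through ((1 + r)/2)^beta", {
  s <- seq_len(8)
  m <- rbind(a = s, b = 2 * s + 1, c = -s, d = s + rep(c(0, 1), 4))
  expr <- expr_fixture(m, genes = rownames(m))
  A <- adjacency_matrix(expr, power = 6)
  expect_equal(A["a", "b"], 1)            # cor = 1
  expect_equal(A["a", "c"], 0)            # cor = -1, signed
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)), rep(1, 4))

  # cor = 0 gives (1/2)^beta in a signed network
  orth <- expr_fixture(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  A2 <- adjacency_matrix(orth, power = 2)
  expect_equal(A2[1, 2], 0.25)

  U <- adjacency_matrix(expr, power = 2, sign_mode = "unsigned")
  expect_equal(U["a", "c"], 1)  # |cor| = 1
  expect_error(adjacency_matrix(expr_fixture(matrix(1, 2, 5)), power = 2),
               "zero-variance")
})

test_that("signed adjacency is monotone increasing in correlation", {
  r <- seq(-0.95, 0.95, by = 0.05)
  a <- ((1 + r) / 2)^7
  expect_true(all(diff(a) > 0))
})

test_that("connectivity sums adjacency without the self-term", {
  A <- diag(5)
  A[upper.tri(A)] <- 1
  A <- pmax(A, t(A))
  dimnames(A) <- list(paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(connectivity(A)$k_total, rep(4, 5))
  expect_equal(connectivity(diag(3))$k_total, rep(0, 3))

  A3 <- diag(3)
  A3[1, 2] <- A3[2, 1] <- 0.5
  A3[1, 3] <- A3[3, 1] <- 0.2
  A3[2, 3] <- A3[3, 2] <- 0.1
  dimnames(A3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(connectivity(A3)$k_total, c(0.7, 0.6, 0.3))

  lab <- tibble::tibble(gene_id = paste0("g", 1:3), module = c("m1", "m1", "m2"))
  k <- connectivity(A3, lab)
  expect_equal(k$k_in, c(0.5, 0.5, 0))
})

test_that("TOM matches hand computations and the brute-force oracle", {
  # isolated perfectly connected pair
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- 1
  dimnames(P) <- list(paste0("g", 1:3), paste0("g", 1:3))
  W <- tom(P)
  expect_equal(W[1, 2], 1)

  # zero off-diagonal adjacency
  Z <- diag(4)
  dimnames(Z) <- list(paste0("g", 1:4), paste0("g", 1:4))
  WZ <- tom(Z)
  expect_equal(unname(WZ[upper.tri(WZ)]), rep(0, 6))

  # three-gene toy: omega_12 = (0.2*0.1 + 0.5) / (0.6 + 1 - 0.5)
  A3 <- diag(3)
  A3[1, 2] <- A3[2, 1] <- 0.5
  A3[1, 3] <- A3[3, 1] <- 0.2
  A3[2, 3] <- A3[3, 2] <- 0.1
  dimnames(A3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(tom(A3)[1, 2], 0.52 / 1.1)

  for (seed in 1:100) {
    A <- random_adjacency(8, seed = seed)
    expect_equal(tom(A), tom_brute_force(A), tolerance = 1e-12)
  }
})

test_that("TOM and adjacency stay symmetric in [0, 1] on synthetic data", {
  cfg <- small_synth(n_samples = 15, sizes = c(25, 20), background = 15, seed = 2)
  sim <- simulate_expression(cfg)
  A <- adjacency_matrix(sim$expr, power = 8)
  W <- tom(A)
  for (M in list(A, W)) {
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("soft-threshold scan reproduces an independent fit and decreasing mean k", {
  cfg <- small_synth(n_samples = 40, sizes = c(60, 50, 40), background = 40,
                     kme = 0.9, seed = 13)
  sim <- simulate_expression(cfg)
  powers <- c(2, 4, 6, 8, 10, 12)
  scan <- pick_soft_threshold(sim$expr, powers = powers, fit_cut = 0.8)
  expect_true(all(diff(scan$scan$mean_k) < 0))

  # independent re-computation of the binned regression for each power
  m <- as_expr_matrix(sim$expr)
  S <- stats::cor(t(m))
  base <- (1 + S) / 2
  diag(base) <- NA
  refit <- sapply(powers, function(p) {
    k <- rowSums(base^p, na.rm = TRUE)
    bins <- cut(k, 10)
    freq <- as.numeric(table(bins)) / length(k)
    kbar <- tapply(k, bins, mean)
    ok <- !is.na(kbar) & freq > 0
    f <- stats::lm(log10(freq[ok]) ~ log10(kbar[ok]))
    -sign(stats::coef(f)[2]) * summary(f)$r.squared
  })
  expect_equal(scan$scan$signed_r2, unname(refit), tolerance = 1e-10)
  sel <- powers[which(refit >= 0.8)]
  expect_equal(scan$selected, if (length(sel)) min(sel) else NA_real_)
  expect_error(pick_soft_threshold(sim$expr, powers = 5), "candidate powers")
})

test_that("the scan reports a sentinel when no power fits", {
  scan <- pick_soft_threshold(
    expr_fixture(matrix(rnorm(40, sd = 1) + rep(rnorm(8), each = 5), 5, 8)),
    powers = c(2, 3), fit_cut = 0.999)
  expect_true(is.na(scan$selected))
  expect_equal(nrow(scan$scan), 2)
})

test_that("tree cut recovers planted modules and small inputs go grey", {
  cfg <- synth_config(n_samples = 60, module_sizes = c(150, 150, 150),
                      n_background_genes = 100, kme_targets = 0.9, seed = 77)
  sim <- simulate_expression(cfg)
  W <- tom(adjacency_matrix(sim$expr, power = 10))
  labels <- cluster_and_cut(W, min_module_size = 100, deep_split = 2)
  j <- dplyr::inner_join(labels, sim$truth$modules, by = "gene_id",
                         suffix = c("", ".true"))
  # score the planted-module separation; unassigned genes on either side
  # are the kME-retention rules' job, not the tree cut's
  j <- j[j$module != "grey" & j$module.true != "grey", ]
  expect_gte(adjusted_rand_index(j$module, j$module.true), 0.9)

  tiny <- random_adjacency(50, seed = 1)
  expect_true(all(cluster_and_cut(tom(tiny), min_module_size = 100)$module == "grey"))
})

test_that("anti-correlated blocks split into two modules in a signed network", {
  set.seed(5)
  e <- rnorm(40)
  up <- t(replicate(30, e + rnorm(40, sd = 0.3)))
  down <- t(replicate(30, -e + rnorm(40, sd = 0.3)))
  expr <- expr_fixture(rbind(up, down))
  W <- tom(adjacency_matrix(expr, power = 6))
  labels <- cluster_and_cut(W, min_module_size = 20, deep_split = 2)
  truth <- rep(c("up", "down"), each = 30)
  expect_equal(length(setdiff(unique(labels$module), "grey")), 2)
  expect_gte(adjusted_rand_index(labels$module, truth), 0.95)
})

test_that("module eigengenes are first principal components", {
  set.seed(3)
  # single-gene module: ME is the standardized profile
  m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expr <- as_expr_tibble(m)
  lab1 <- tibble::tibble(gene_id = "g1", module = "solo")
  me1 <- module_eigengene(expr[1, ], lab1)
  expect_equal(abs(stats::cor(me1$me$solo, as.numeric(m[1, ]))), 1, tolerance = 1e-12)
  expect_equal(me1$var_explained$var_explained, 1)

  # identical genes: variance explained 1, ME = common profile
  same <- expr_fixture(matrix(rep(rnorm(12), each = 5), 5, 12))
  lab2 <- tibble::tibble(gene_id = same$gene_id, module = "dup")
  me2 <- module_eigengene(same, lab2)
  expect_equal(me2$var_explained$var_explained, 1, tolerance = 1e-12)

  # random module: variance explained equals top eigenvalue share of the
  # gene-gene covariance of standardized profiles (independent eigensolver)
  set.seed(8)
  G <- matrix(rnorm(20 * 15), 20, 15)
  expr3 <- expr_fixture(G)
  lab3 <- tibble::tibble(gene_id = expr3$gene_id, module = "rand")
  me3 <- module_eigengene(expr3, lab3)
  Gs <- t(scale(t(G)))
  ev <- eigen(Gs %*% t(Gs), symmetric = TRUE)$values
  expect_equal(me3$var_explained$var_explained, ev[1] / sum(ev), tolerance = 1e-10)

  # sign orientation: positively aligned with the mean profile
  expect_gte(stats::cor(me3$me$rand, colMeans(t(scale(t(G))))), 0)
})

test_that("no unit combination of module genes beats the eigengene", {
  set.seed(14)
  G <- matrix(rnorm(30 * 12), 30, 12)
  expr <- expr_fixture(G)
  lab <- tibble::tibble(gene_id = expr$gene_id, module = "m")
  me <- module_eigengene(expr, lab)
  Gs <- t(scale(t(G)))
  top_share <- me$var_explained$var_explained
  for (i in 1:25) {
    w <- rnorm(30)
    w <- w / sqrt(sum(w^2))
    proj <- as.numeric(w %*% Gs)
    share <- sum(proj^2) / sum(Gs^2)
    expect_lte(share, top_share + 1e-10)
  }
})

test_that("membership rules reassign weak genes and disband coreless modules", {
  set.seed(6)
  n <- 40
  e <- rnorm(n)
  strong <- t(sapply(1:50, function(i) 0.95 * e + sqrt(1 - 0.95^2) * rnorm(n)))
  weak <- 0.1 * e + sqrt(1 - 0.01) * rnorm(n)
  m <- rbind(strong, weak)
  expr <- expr_fixture(m)
  lab <- tibble::tibble(gene_id = expr$gene_id, module = "m1")
  res <- apply_membership_rules(expr, lab, min_module_size = 30)
  out <- stats::setNames(res$labels$module, res$labels$gene_id)
  expect_equal(unname(out["g51"]), "grey")     # kME ~ 0.1 < 0.3
  expect_true(all(out[1:50] == "m1"))          # high-kME members stay

  # module whose best genes stall below the core threshold is disbanded
  weak_all <- t(sapply(1:60, function(i) 0.4 * e + sqrt(1 - 0.16) * rnorm(n)))
  expr2 <- expr_fixture(weak_all)
  lab2 <- tibble::tibble(gene_id = expr2$gene_id, module = "m1")
  res2 <- apply_membership_rules(expr2, lab2, min_module_size = 100,
                                 core_kme = 0.9)
  expect_true(all(res2$labels$module == "grey"))
  expect_equal(res2$disbanded, "m1")
})

test_that("build_network converges with zero grey on clean modular data", {
  cfg <- synth_config(n_samples = 50, module_sizes = c(120, 100),
                      n_background_genes = 0, kme_targets = 0.9, seed = 19)
  sim <- simulate_expression(cfg)
  net <- build_network(sim$expr, power = 10, min_module_size = 80, deep_split = 2)
  expect_true(net$converged)
  expect_lte(nrow(net$iterations), 3)
  expect_equal(sum(net$iterations$n_grey[nrow(net$iterations)]), 0)
  expect_setequal(unique(net$modules$module), c("turquoise", "blue"))
  j <- dplyr::inner_join(net$modules, sim$truth$modules, by = "gene_id",
                         suffix = c("", ".true"))
  expect_gte(adjusted_rand_index(j$module, j$module.true), 0.95)
  # kIN never exceeds kTotal
  expect_true(all(net$modules$k_in <= net$modules$k_total + 1e-12))
  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(glance(net)$n_modules, 2L)
})

test_that("pure-noise data terminates with everything unassigned", {
  set.seed(23)
  expr <- expr_fixture(matrix(rnorm(300 * 20), 300, 20))
  net <- build_network(expr, power = 10, min_module_size = 100, deep_split = 2,
                       max_iter = 5)
  expect_equal(nrow(net$modules), 0)
})
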