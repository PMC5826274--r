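#' Configuration for the synthetic study generator
#'
#' Describes a synthetic bulk RNA-seq study with planted coexpression
#' modules, behavioral traits coupled to module eigengenes, and a second
#' condition (a region/age analogue) in which a chosen subset of modules is
#' preserved while the rest lose their coexpression structure. The defaults
#' emulate the design of the songbird basal-ganglia study this package
#' supports: 19 samples, ~13,000 genes organized into modules of 100-2,000
#' genes, and four song-related traits.
#'
#' @param n_samples Number of samples (animals). Default 19.
#' @param module_sizes Integer vector of planted module sizes, largest
#'   first. Modules are labelled by the conventional size-ranked color
#'   palette (turquoise, blue, brown, ...).
#' @param n_background_genes Genes with no planted coexpression.
#' @param kme_targets Target gene-eigengene correlation (module membership)
#'   per module; recycled.
#' @param trait_couplings Tibble with columns `trait`, `module`, `rho`
#'   giving the target Pearson correlation between each behavioral trait
#'   and a module's latent eigengene.
#' @param preserved_modules Module labels whose coexpression is retained in
#'   condition 2; all other planted modules are scrambled there.
#' @param noise_sd Standard deviation of per-gene residual noise relative
#'   to the unit-variance latent eigengene. At the default 1 the realized
#'   module membership equals `kme_targets` in expectation.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 19,
                         module_sizes = c(2000, 1200, 800, 500, 300, 200, 150, 100),
                         n_background_genes = 7750,
                         kme_targets = 0.8,
                         trait_couplings = NULL,
                         preserved_modules = NULL,
                         noise_sd = 1,
                         seed = 1) {
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) == 0 || sum(module_sizes) == 0) {
    stop("module sizes must sum to a positive count", call. = FALSE)
  }
  if (any(module_sizes < 1)) stop("module sizes must be >= 1", call. = FALSE)
  if (n_samples < 4) {
    stop("n_samples must be >= 4; correlations are undefined downstream", call. = FALSE)
  }
  labels <- module_palette(length(module_sizes))
  kme_targets <- rep_len(kme_targets, length(module_sizes))
  if (any(abs(kme_targets) > 1)) stop("|kme_targets| must be <= 1", call. = FALSE)
  if (is.null(trait_couplings)) {
    k <- length(labels)
    trait_couplings <- tibble::tibble(
      trait = c("motifs", "tutor_similarity", "variability_induction", "motif_identity"),
      module = labels[c(1, min(2, k), min(3, k), min(4, k))],
      rho = c(0.9, 0.9, -0.7, 0.7)
    )
  }
  stopifnot(all(c("trait", "module", "rho") %in% names(trait_couplings)))
  if (any(abs(trait_couplings$rho) > 1)) stop("|rho| must be <= 1", call. = FALSE)
  if (!all(trait_couplings$module %in% labels)) {
    stop("trait_couplings reference unknown module labels", call. = FALSE)
  }
  if (is.null(preserved_modules)) {
    # by default the second-ranked (learning analogue) module is scrambled
    preserved_modules <- setdiff(labels, labels[min(2, length(labels))])
  }
  if (!all(preserved_modules %in% labels)) {
    stop("unknown module label in preserved_modules", call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples),
    module_sizes = stats::setNames(module_sizes, labels),
    n_background_genes = as.integer(n_background_genes),
    kme_targets = stats::setNames(kme_targets, labels),
    trait_couplings = tibble::as_tibble(trait_couplings),
    preserved_modules = preserved_modules,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# draw per-gene loadings near the module's kME target
draw_loadings <- function(target, n) {
  r <- target + stats::rnorm(n, sd = 0.03)
  sign(target + (target == 0)) * pmin(pmax(abs(r), 0), 0.999 + 0.001 * (abs(target) == 1))
}

#' Simulate a planted-module expression matrix
#'
#' Each module is driven by a latent standardized eigengene \eqn{E_m}
#' (i.i.d. standard normal over samples). A gene of module m with loading
#' \eqn{r_i} is generated as
#' \eqn{x_i = \mu_i + s_i (r_i E_m + \sqrt{1-r_i^2}\, \sigma z)},
#' so that at `noise_sd` \eqn{\sigma = 1} its correlation with the
#' eigengene is \eqn{r_i} in expectation. Background genes are independent
#' noise. Gene-level means and scales mimic log2 TPM data.
#'
#' @param config A [synth_config()].
#' @return List with `expr` (expression tibble) and `truth` (ground-truth
#'   list: `modules`, `eigengenes`, `loadings`, `gene_means`, `gene_scales`,
#'   `preserved`, `trait_couplings`, `config`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)
  labels <- names(config$module_sizes)
  n <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  n_mod_genes <- sum(config$module_sizes)
  n_genes <- n_mod_genes + config$n_background_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  module_of <- c(rep(labels, times = config$module_sizes),
                 rep("grey", config$n_background_genes))

  E <- matrix(stats::rnorm(length(labels) * n), nrow = length(labels),
              dimnames = list(labels, sample_ids))
  E <- t(scale(t(E)))  # exact mean 0, sd 1 per eigengene

  loadings <- numeric(n_genes)
  signal <- matrix(0, nrow = n_genes, ncol = n)
  idx0 <- 0
  for (m in seq_along(labels)) {
    sz <- config$module_sizes[m]
    rows <- idx0 + seq_len(sz)
    r <- draw_loadings(config$kme_targets[m], sz)
    loadings[rows] <- r
    z <- matrix(stats::rnorm(sz * n), nrow = sz)
    signal[rows, ] <- r %o% E[m, ] + sqrt(1 - r^2) * config$noise_sd * z
    idx0 <- idx0 + sz
  }
  if (config$n_background_genes > 0) {
    rows <- idx0 + seq_len(config$n_background_genes)
    signal[rows, ] <- config$noise_sd *
      matrix(stats::rnorm(config$n_background_genes * n), ncol = n)
  }
  gene_means <- stats::rnorm(n_genes, mean = 6, sd = 2)
  gene_scales <- stats::runif(n_genes, 0.5, 2)
  expr_mat <- gene_means + gene_scales * signal
  dimnames(expr_mat) <- list(gene_ids, sample_ids)

  truth <- list(
    modules = tibble::tibble(gene_id = gene_ids, module = module_of),
    eigengenes = dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                                  tibble::as_tibble(t(E))),
    loadings = tibble::tibble(gene_id = gene_ids, loading = loadings),
    gene_means = stats::setNames(gene_means, gene_ids),
    gene_scales = stats::setNames(gene_scales, gene_ids),
    preserved = tibble::tibble(
      module = labels, preserved = labels %in% config$preserved_modules),
    trait_couplings = config$trait_couplings,
    config = config
  )
  list(expr = as_expr_tibble(expr_mat), truth = truth)
}

#' Simulate behavioral traits coupled to planted eigengenes
#'
#' Each trait is a linear transform of
#' \eqn{\rho E_m + \sqrt{1-\rho^2} z}, placed on a realistic scale:
#' motifs sung in 2 h (non-negative integer count), tutor similarity and
#' motif identity (percentages), and variability induction (an effect size
#' in (-1, 1)). Linear scaling preserves the target Pearson correlation.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param config The same [synth_config()].
#' @return Tibble with `sample_id` and the four trait columns.
#' @export
simulate_traits <- function(truth, config) {
  withr::local_seed(derive_seed(config$seed, 101L))
  E <- t(as_expr_matrix(dplyr::rename(truth$eigengenes, gene_id = "sample_id")))
  n <- nrow(truth$eigengenes)
  out <- tibble::tibble(sample_id = truth$eigengenes$sample_id)
  scales <- list(
    motifs = function(x) round(pmax(0, 250 + 120 * x)),
    tutor_similarity = function(x) pmin(100, pmax(0, 65 + 12 * x)),
    variability_induction = function(x) pmin(0.99, pmax(-0.99, -0.05 + 0.08 * x)),
    motif_identity = function(x) pmin(100, pmax(0, 60 + 12 * x))
  )
  for (i in seq_len(nrow(config$trait_couplings))) {
    tr <- config$trait_couplings$trait[i]
    rho <- config$trait_couplings$rho[i]
    e <- E[config$trait_couplings$module[i], ]
    latent <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n)
    f <- scales[[tr]] %||% identity
    out[[tr]] <- f(latent)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a negative-binomial read-count matrix from expression values
#'
#' Converts per-gene abundances into expected read counts in proportion to
#' abundance times gene length within each sample, then draws
#' negative-binomial counts (Poisson in the `dispersion = 0` limit), so
#' that TPM computed from the counts recovers the input relative
#' abundances in expectation.
#'
#' @param expr Expression tibble; values are log2 abundances unless
#'   `log2_input = FALSE`, in which case they are linear-scale abundances
#'   (zeros allowed and guaranteed to give zero counts).
#' @param gene_lengths Tibble (`gene_id`, `length`) or named vector of
#'   positive transcript lengths in base pairs.
#' @param library_sizes Expected total reads per sample; scalar recycled.
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives
#'   Poisson counts.
#' @param seed Integer seed.
#' @param log2_input Interpret `expr` values as log2 abundances?
#' @return Count tibble (`gene_id` plus one integer column per sample).
#' @export
simulate_counts <- function(expr, gene_lengths, library_sizes = 5e6,
                            dispersion = 0.05, seed = 1, log2_input = TRUE) {
  m <- as_expr_matrix(expr)
  len <- if (is.data.frame(gene_lengths)) {
    stats::setNames(gene_lengths$length, gene_lengths$gene_id)[rownames(m)]
  } else {
    gene_lengths[rownames(m)]
  }
  if (anyNA(len) || any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  ab <- if (log2_input) 2^m else m
  if (any(ab < 0)) stop("abundances must be non-negative", call. = FALSE)
  lib <- rep_len(library_sizes, ncol(m))
  withr::local_seed(derive_seed(seed, 0L))
  counts <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    w <- ab[, j] * len
    mu <- lib[j] * w / sum(w)
    counts[, j] <- if (dispersion <= 0) {
      stats::rpois(nrow(m), lambda = mu)
    } else {
      stats::rnbinom(nrow(m), mu = mu, size = 1 / dispersion)
    }
  }
  as_expr_tibble(counts)
}

#' Simulate the second-condition expression matrix
#'
#' Re-generates the study in a second condition (another brain region or
#' age). Preserved modules keep their gene loadings and are re-drawn from
#' fresh latent eigengenes, so their coexpression structure recurs in new
#' samples. Non-preserved modules have their loadings permuted across the
#' module's genes and attached to independent per-gene latent factors:
#' every gene keeps its mean and marginal variance, but the shared factor
#' — and with it all within-module coexpression — is gone.
#'
#' @param expr Condition-1 expression (unused except for dimension checks;
#'   kept for pipeline symmetry).
#' @param truth Ground truth from [simulate_expression()].
#' @param config The [synth_config()]; `preserved_modules` decides which
#'   modules persist.
#' @param n_samples Samples in condition 2 (default: same as condition 1).
#' @param attenuation Optional named vector of per-module loading scale
#'   factors in \[0, 1\] applied to preserved modules in condition 2;
#'   values below 1 weaken (attenuate) the module's coexpression without
#'   destroying it. Unnamed modules keep scale 1.
#' @return Expression tibble with the same genes and new sample ids
#'   (`C2S..`).
#' @export
simulate_condition2 <- function(expr, truth, config, n_samples = config$n_samples,
                                attenuation = NULL) {
  stopifnot(inherits(config, "synth_config"))
  labels <- names(config$module_sizes)
  if (!all(config$preserved_modules %in% labels)) {
    stop("unknown module label in preserved_modules", call. = FALSE)
  }
  withr::local_seed(derive_seed(config$seed, 202L))
  n <- as.integer(n_samples)
  sample_ids <- sprintf("C2S%02d", seq_len(n))
  gene_ids <- truth$modules$gene_id
  module_of <- truth$modules$module
  loading <- stats::setNames(truth$loadings$loading, gene_ids)

  E2 <- matrix(stats::rnorm(length(labels) * n), nrow = length(labels),
               dimnames = list(labels, sample_ids))
  E2 <- t(scale(t(E2)))

  signal <- matrix(0, nrow = length(gene_ids), ncol = n)
  for (m in labels) {
    rows <- which(module_of == m)
    r <- loading[rows]
    z <- matrix(stats::rnorm(length(rows) * n), nrow = length(rows))
    if (m %in% config$preserved_modules) {
      att <- if (!is.null(attenuation) && m %in% names(attenuation)) attenuation[[m]] else 1
      r <- r * att
      signal[rows, ] <- r %o% E2[m, ] + sqrt(1 - r^2) * config$noise_sd * z
    } else {
      r <- sample(r)  # permute loadings across the module's genes
      u <- matrix(stats::rnorm(length(rows) * n), nrow = length(rows))
      signal[rows, ] <- r * u + sqrt(1 - r^2) * config$noise_sd * z
    }
  }
  bg <- which(module_of == "grey")
  if (length(bg) > 0) {
    signal[bg, ] <- config$noise_sd * matrix(stats::rnorm(length(bg) * n), ncol = n)
  }
  expr_mat <- truth$gene_means[gene_ids] + truth$gene_scales[gene_ids] * signal
  dimnames(expr_mat) <- list(gene_ids, sample_ids)
  as_expr_tibble(expr_mat)
}

#' Simulate a term -> gene annotation table
#'
#' Enriched terms draw most of their genes from one planted module and get
#' small p-values; null terms draw genes at random with uniform p-values.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param n_terms Total number of terms.
#' @param genes_per_term Genes annotated per term.
#' @param frac_enriched Fraction of terms enriched in a planted module.
#' @param seed Integer seed.
#' @return Tibble: `term_id`, `category`, `p_value`, `target_module`
#'   (`NA` for null terms), and list-column `genes`.
#' @export
simulate_annotations <- function(truth, n_terms = 60, genes_per_term = 15,
                                 frac_enriched = 0.7, seed = 1) {
  withr::local_seed(derive_seed(seed, 303L))
  labels <- setdiff(unique(truth$modules$module), "grey")
  all_genes <- truth$modules$gene_id
  n_enr <- round(frac_enriched * n_terms)
  rows <- purrr::map(seq_len(n_terms), function(i) {
    enriched <- i <= n_enr
    if (enriched) {
      mod <- labels[(i - 1) %% length(labels) + 1]
      pool <- truth$modules$gene_id[truth$modules$module == mod]
      n_in <- min(length(pool), ceiling(0.8 * genes_per_term))
      genes <- c(sample(pool, n_in),
                 sample(setdiff(all_genes, pool), genes_per_term - n_in))
      p <- stats::runif(1, 1e-6, 0.05)
    } else {
      mod <- NA_character_
      genes <- sample(all_genes, genes_per_term)
      p <- stats::runif(1, 0.05, 1)
    }
    tibble::tibble(
      term_id = sprintf("T%03d", i),
      category = c("GO", "pathway", "disease")[(i - 1) %% 3 + 1],
      p_value = p, target_module = mod, genes = list(genes)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a confidence-scored gene-pair interaction table
#'
#' Samples gene pairs within and across planted modules and assigns
#' interaction confidences in \[0, 1\]; a designated subset is
#' high-confidence (>= 0.9), mirroring curated protein-interaction scores.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param n_edges Number of unordered gene pairs.
#' @param frac_high_conf Fraction drawn from the high-confidence range.
#' @param seed Integer seed.
#' @return Tibble: `gene_i`, `gene_j`, `confidence`, `high_confidence`.
#' @export
simulate_interactions <- function(truth, n_edges = 400, frac_high_conf = 0.25,
                                  seed = 1) {
  withr::local_seed(derive_seed(seed, 404L))
  mod_genes <- truth$modules$gene_id[truth$modules$module != "grey"]
  pairs <- matrix(character(0), ncol = 2)
  seen <- character(0)
  while (nrow(pairs) < n_edges) {
    cand <- matrix(sample(mod_genes, 2 * (n_edges - nrow(pairs)), replace = TRUE), ncol = 2)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    key <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
    keep <- !duplicated(key) & !(key %in% seen)
    cand <- cand[keep, , drop = FALSE]
    seen <- c(seen, key[keep])
    pairs <- rbind(pairs, cand)
  }
  n_hi <- round(frac_high_conf * n_edges)
  conf <- c(stats::runif(n_hi, 0.9, 1), stats::runif(n_edges - n_hi, 0.15, 0.9))
  conf <- conf[sample.int(n_edges)]
  tibble::tibble(
    gene_i = pmin(pairs[, 1], pairs[, 2]),
    gene_j = pmax(pairs[, 1], pairs[, 2]),
    confidence = conf,
    high_confidence = conf >= 0.9
  )
}

#' Simulate promoter sequences with planted motif instances
#'
#' Generates uniform-background promoters and plants, at rate
#' `motif_rate`, one motif instance per promoter sampled position-wise
#' from the PWM's base probabilities, recording the 0-based offset and the
#' planted instance's true relative score.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param n Number of promoters.
#' @param motif_rate Probability a promoter carries one planted instance.
#' @param promoter_length Promoter length in base pairs (default 1000).
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector) and `planted`
#'   (tibble `seq_id`, `offset`, `motif`, `relative_score`).
#' @export
simulate_promoters <- function(pwm, n = 200, motif_rate = 0.5,
                               promoter_length = 1000, seed = 1) {
  stopifnot(inherits(pwm, "songnet_pwm"))
  L <- ncol(pwm$weights)
  if (L > promoter_length) stop("motif longer than promoter", call. = FALSE)
  withr::local_seed(derive_seed(seed, 505L))
  bases <- c("A", "C", "G", "T")
  seq_ids <- sprintf("P%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(bases, promoter_length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- seq_ids
  planted <- list()
  for (i in seq_len(n)) {
    if (stats::runif(1) < motif_rate) {
      inst <- vapply(seq_len(L), function(p) sample(bases, 1, prob = pwm$prob[, p]),
                     character(1))
      inst <- paste(inst, collapse = "")
      off <- sample.int(promoter_length - L + 1, 1) - 1L
      substr(seqs[i], off + 1, off + L) <- inst
      planted[[length(planted) + 1]] <- tibble::tibble(
        seq_id = seq_ids[i], offset = off, motif = inst,
        relative_score = relative_pwm_score(pwm, inst)
      )
    }
  }
  planted <- if (length(planted)) dplyr::bind_rows(planted) else
    tibble::tibble(seq_id = character(), offset = integer(),
                   motif = character(), relative_score = numeric())
  list(sequences = seqs, planted = planted)
}
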