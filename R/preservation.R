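#' Intersect two expression datasets on their common genes
#'
#' Cross-dataset preservation statistics are computed only over genes
#' present in both datasets; the intersection is deterministic (sorted).
#'
#' @param expr_ref,expr_test Expression tibbles.
#' @return List of class `common_gene_view`: `genes` (sorted common ids),
#'   `n_dropped_ref`, `n_dropped_test`.
#' @export
intersect_networks <- function(expr_ref, expr_test) {
  g <- sort(intersect(expr_ref$gene_id, expr_test$gene_id))
  if (length(g) == 0) stop("no genes shared between the two datasets", call. = FALSE)
  structure(list(
    genes = g,
    n_dropped_ref = length(setdiff(expr_ref$gene_id, g)),
    n_dropped_test = length(setdiff(expr_test$gene_id, g))
  ), class = "common_gene_view")
}

# The six preservation statistics. Density statistics (first three) are
# computed on the test-side gene set; connectivity statistics (last
# three) compare the reference-side set against the test-side set
# position by position. Observed statistics use the module's genes on
# both sides; the permutation null keeps the module on the reference
# side and substitutes a random same-size gene set on the test side,
# which breaks the gene correspondence.
preservation_stats <- function(mref, mtest, idx_ref, idx_test, beta_ref, beta_test) {
  eig <- function(block) {
    G <- scale_rows(block)
    G[is.na(G)] <- 0
    sv <- svd(G)
    v1 <- as.numeric(scale(sv$v[, 1]))
    if (stats::cor(v1, colMeans(G)) < 0) v1 <- -v1
    list(me = v1, var_explained = sv$d[1]^2 / sum(sv$d^2),
         kme = as.vector(stats::cor(t(block), v1, use = "pairwise.complete.obs")))
  }
  rt <- mtest[idx_test, , drop = FALSE]
  rr <- mref[idx_ref, , drop = FALSE]
  ct <- stats::cor(t(rt), use = "pairwise.complete.obs")
  cr <- stats::cor(t(rr), use = "pairwise.complete.obs")
  at <- ((1 + ct) / 2)^beta_test
  ar <- ((1 + cr) / 2)^beta_ref
  et <- eig(rt)
  er <- eig(rr)
  ut <- upper.tri(ct)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c(
    mean_adjacency = mean(at[ut]),
    var_explained = et$var_explained,
    mean_kme = mean(abs(et$kme)),
    cor_kin = safe_cor(rowSums(ar) - diag(ar), rowSums(at) - diag(at)),
    cor_kme = safe_cor(er$kme, et$kme),
    cor_cor = safe_cor(cr[ut], ct[ut])
  )
}

#' Permutation module-preservation statistics (Zsummary)
#'
#' Quantifies how well each reference module's coexpression structure
#' recurs in a test dataset. Three density statistics (mean within-module
#' signed adjacency, eigengene variance explained, mean |kME|, all in the
#' test data) assess whether the module is still a tight cluster; three
#' connectivity statistics (correlations between datasets of intramodular
#' connectivity, kME, and the vectorized within-module correlation
#' matrix) assess whether the same genes are connected the same way.
#' Each observed statistic is standardized against `n_perm` permutations
#' in which a random same-size gene set from the common-gene universe
#' replaces the module on the test side (the reference side keeps the
#' module's genes, so the gene correspondence is broken under the null):
#' \eqn{Z = (obs - mean_{null}) / sd_{null}}. Zdensity and Zconnectivity
#' are the medians of their three Zs and Zsummary is their mean; the
#' conventional interpretation thresholds are 2 (low) and 10 (high)
#' preservation. Median rank ranks modules by each observed statistic and
#' takes the per-module median.
#'
#' @param expr_ref Reference expression tibble (where modules were defined).
#' @param expr_test Test expression tibble.
#' @param labels_ref Tibble (`gene_id`, `module`) from the reference
#'   network; grey is skipped.
#' @param beta_test Soft power for test-data adjacency.
#' @param beta_ref Soft power for reference-data adjacency; defaults to
#'   `beta_test`.
#' @param n_perm Number of permutations (>= 50); default 200.
#' @param seed Integer seed for the permutation draws.
#' @param min_module_size Modules with fewer common genes are skipped with
#'   a warning; default 3.
#' @return Object of class `module_preservation`: `report` tibble with
#'   per-module size, observed statistics, Zdensity, Zconnectivity,
#'   Zsummary and median_rank, plus `n_perm`, `seed`, `thresholds`.
#' @export
module_preservation <- function(expr_ref, expr_test, labels_ref, beta_test,
                                beta_ref = beta_test, n_perm = 200, seed = 1,
                                min_module_size = 3) {
  if (n_perm < 50) stop("n_perm must be >= 50", call. = FALSE)
  common <- intersect_networks(expr_ref, expr_test)
  mref <- as_expr_matrix(expr_ref)[common$genes, , drop = FALSE]
  mtest <- as_expr_matrix(expr_test)[common$genes, , drop = FALSE]
  lab <- stats::setNames(labels_ref$module, labels_ref$gene_id)
  lab <- lab[names(lab) %in% common$genes]
  mods <- setdiff(unique(lab), "grey")
  sets <- lapply(mods, function(m) which(common$genes %in% names(lab)[lab == m]))
  names(sets) <- mods
  small <- lengths(sets) < min_module_size
  if (any(small)) {
    warning("skipping module(s) with < ", min_module_size, " common genes: ",
            paste(mods[small], collapse = ", "))
    sets <- sets[!small]
    mods <- mods[!small]
  }
  if (length(sets) == 0) stop("no modules to assess", call. = FALSE)

  withr::local_seed(derive_seed(seed, 0L))
  n_genes <- length(common$genes)
  stat_names <- c("mean_adjacency", "var_explained", "mean_kme",
                  "cor_kin", "cor_kme", "cor_cor")
  obs <- t(vapply(sets, function(idx)
    preservation_stats(mref, mtest, idx, idx, beta_ref, beta_test),
    numeric(length(stat_names))))

  z <- matrix(NA_real_, nrow = length(sets), ncol = length(stat_names),
              dimnames = list(mods, stat_names))
  for (i in seq_along(sets)) {
    s <- length(sets[[i]])
    null <- t(vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n_genes, s)
      preservation_stats(mref, mtest, sets[[i]], idx, beta_ref, beta_test)
    }, numeric(length(stat_names))))
    mu <- colMeans(null, na.rm = TRUE)
    sdv <- apply(null, 2, stats::sd, na.rm = TRUE)
    zi <- (obs[i, ] - mu) / sdv
    zi[!is.finite(zi)] <- 0  # degenerate null spread
    z[i, ] <- zi
  }
  z_density <- apply(z[, 1:3, drop = FALSE], 1, stats::median)
  z_connectivity <- apply(z[, 4:6, drop = FALSE], 1, stats::median)
  z_summary <- (z_density + z_connectivity) / 2
  # rank modules (1 = most preserved) by each observed statistic
  ranks <- apply(obs, 2, function(x) rank(-x, ties.method = "average"))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  median_rank <- apply(ranks, 1, stats::median)

  report <- dplyr::bind_cols(
    tibble::tibble(module = mods, size = lengths(sets)),
    tibble::as_tibble(obs),
    tibble::tibble(z_density = unname(z_density),
                   z_connectivity = unname(z_connectivity),
                   z_summary = unname(z_summary),
                   median_rank = unname(median_rank))
  )
  structure(list(
    report = report,
    n_perm = n_perm,
    seed = seed,
    beta_ref = beta_ref,
    beta_test = beta_test,
    thresholds = c(low = 2, high = 10),
    n_common_genes = n_genes
  ), class = "module_preservation")
}

#' @export
print.module_preservation <- function(x, ...) {
  cat(sprintf("Module preservation over %d common genes (%d permutations)\n",
              x$n_common_genes, x$n_perm))
  print(dplyr::select(x$report, "module", "size", "z_density",
                      "z_connectivity", "z_summary", "median_rank"),
        n = nrow(x$report))
  invisible(x)
}

#' @exportS3Method
tidy.module_preservation <- function(x, ...) x$report

#' @exportS3Method
glance.module_preservation <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$report),
    n_common_genes = x$n_common_genes,
    n_perm = x$n_perm,
    n_high_preserved = sum(x$report$z_summary > x$thresholds["high"]),
    n_low_preserved = sum(x$report$z_summary < x$thresholds["low"])
  )
}

#' @exportS3Method
autoplot.module_preservation <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$size, y = .data$z_summary,
                               label = .data$module)) +
    ggplot2::geom_hline(yintercept = object$thresholds, linetype = "dashed",
                        color = c("blue", "darkgreen")) +
    ggplot2::geom_point(ggplot2::aes(color = .data$module), size = 3,
                        show.legend = FALSE) +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Module size (genes)", y = "Zsummary",
                  title = "Module preservation",
                  subtitle = "dashed lines: low (2) and high (10) preservation") +
    ggplot2::theme_minimal()
}
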