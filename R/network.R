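#' Correlation-based weighted adjacency matrix
#'
#' Raises the gene-gene Pearson correlation to a soft-threshold power.
#' Signed networks map correlation through `(1 + cor)/2` first, so
#' perfectly anti-correlated genes get adjacency 0 rather than 1;
#' unsigned networks use `|cor|`.
#'
#' @param expr Expression tibble; correlations use pairwise-complete
#'   samples, so masked (`NA`) cells are tolerated.
#' @param power Soft-threshold power beta (>= 1).
#' @param sign_mode `"signed"` (default) or `"unsigned"`.
#' @return Symmetric gene x gene matrix in \[0, 1\] with unit diagonal and
#'   attributes `power` and `sign_mode`.
#' @export
adjacency_matrix <- function(expr, power, sign_mode = c("signed", "unsigned")) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(power >= 1)
  m <- as_expr_matrix(expr)
  if (ncol(m) < 4) stop("need >= 4 samples", call. = FALSE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  if (any(is.na(sd) | sd == 0)) {
    stop("zero-variance gene(s); remove before network construction", call. = FALSE)
  }
  S <- stats::cor(t(m), use = "pairwise.complete.obs")
  A <- if (sign_mode == "signed") ((1 + S) / 2)^power else abs(S)^power
  diag(A) <- 1
  A[A > 1] <- 1
  A[A < 0] <- 0
  attr(A, "power") <- power
  attr(A, "sign_mode") <- sign_mode
  A
}

#' Whole-network and intramodular connectivity
#'
#' Connectivity of gene i is the sum of its adjacencies to all other
#' genes (`k_total`), or to the other genes sharing its module label
#' (`k_in`). The self-adjacency is excluded.
#'
#' @param A Adjacency matrix from [adjacency_matrix()].
#' @param labels Optional tibble (`gene_id`, `module`); when supplied,
#'   `k_in` is computed within each gene's own module.
#' @return Tibble: `gene_id`, `k_total`, and `k_in` if labels were given.
#' @export
connectivity <- function(A, labels = NULL) {
  out <- tibble::tibble(gene_id = rownames(A), k_total = unname(rowSums(A) - diag(A)))
  if (!is.null(labels)) {
    lab <- stats::setNames(labels$module, labels$gene_id)[rownames(A)]
    k_in <- numeric(nrow(A))
    for (m in unique(lab)) {
      idx <- which(lab == m)
      k_in[idx] <- rowSums(A[idx, idx, drop = FALSE]) - diag(A)[idx]
    }
    out$k_in <- k_in
  }
  out
}

#' Topological overlap matrix (TOM)
#'
#' Interconnectedness of genes i and j combining their direct adjacency
#' and shared neighbors:
#' \eqn{\omega_{ij} = (l_{ij} + a_{ij}) / (\min\{k_i, k_j\} + 1 - a_{ij})}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and connectivity k
#' excluding the self-term. The diagonal is 1 by convention.
#'
#' @param A Adjacency matrix from [adjacency_matrix()].
#' @return Symmetric TOM matrix in \[0, 1\].
#' @export
tom <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  k <- rowSums(A) - diag(A)
  L <- A %*% A
  # (A %*% A)_ij counts u = i and u = j: subtract a_ii*a_ij + a_ij*a_jj = 2*a_ij
  L <- L - 2 * A
  mink <- outer(k, k, pmin)
  W <- (L + A) / (mink + 1 - A)
  diag(W) <- 1
  W[W > 1] <- 1
  W[W < 0] <- 0
  dimnames(W) <- dimnames(A)
  W
}

# scale-free topology fit for a connectivity vector: bin k into nb
# equal-width bins and regress log10 bin frequency on log10 mean bin k
scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) return(list(signed_r2 = NA_real_, slope = NA_real_))
  bins <- cut(k, breaks = n_bins)
  freq <- as.numeric(table(bins)) / length(k)
  kbar <- tapply(k, bins, mean)
  ok <- !is.na(kbar) & freq > 0 & kbar > 0
  if (sum(ok) < 2) return(list(signed_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kbar[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' Scan candidate soft-threshold powers for scale-free topology
#'
#' For each candidate power, computes the connectivity distribution of the
#' resulting adjacency and its scale-free model fit (signed R^2 of
#' log-frequency on log-connectivity over 10 equal-width bins). The
#' selected power is the smallest candidate whose signed R^2 reaches
#' `fit_cut`; `NA` if none does.
#'
#' @param expr Expression tibble.
#' @param powers Candidate powers; default `c(1:10, seq(12, 20, 2))`.
#' @param fit_cut Signed scale-free R^2 criterion; default 0.8.
#' @param sign_mode `"signed"` or `"unsigned"`.
#' @return Object of class `soft_threshold_scan`: list with `scan`
#'   (tibble: power, signed_r2, slope, mean_k, median_k, max_k),
#'   `selected`, `fit_cut`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                                fit_cut = 0.8, sign_mode = c("signed", "unsigned")) {
  sign_mode <- match.arg(sign_mode)
  if (length(powers) < 2) stop("need >= 2 candidate powers", call. = FALSE)
  m <- as_expr_matrix(expr)
  S <- stats::cor(t(m), use = "pairwise.complete.obs")
  base <- if (sign_mode == "signed") (1 + S) / 2 else abs(S)
  diag(base) <- NA
  rows <- purrr::map(sort(powers), function(p) {
    A <- base^p
    k <- rowSums(A, na.rm = TRUE)
    f <- scale_free_fit(k)
    tibble::tibble(power = p, signed_r2 = f$signed_r2, slope = f$slope,
                   mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  scan <- dplyr::bind_rows(rows)
  hit <- scan$power[!is.na(scan$signed_r2) & scan$signed_r2 >= fit_cut]
  structure(list(
    scan = scan,
    selected = if (length(hit)) min(hit) else NA_real_,
    fit_cut = fit_cut,
    sign_mode = sign_mode
  ), class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (", x$sign_mode, " network, fit cut ", x$fit_cut, ")\n",
      sep = "")
  print(x$scan, n = nrow(x$scan))
  cat("selected power: ", if (is.na(x$selected)) "none" else x$selected, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.soft_threshold_scan <- function(x, ...) x$scan

#' @exportS3Method
glance.soft_threshold_scan <- function(x, ...) {
  tibble::tibble(selected_power = x$selected, fit_cut = x$fit_cut,
                 n_powers = nrow(x$scan), sign_mode = x$sign_mode)
}

#' Hierarchical clustering of the TOM with a dynamic-height cut
#'
#' Average-linkage clustering on the dissimilarity `1 - TOM`, cut at a
#' `deep_split`-dependent fraction of the dendrogram's merge-height range
#' (higher `deep_split` means a lower cut and finer modules). Branches
#' smaller than `min_module_size` are assigned to the reserved "grey"
#' label.
#'
#' @param tomm TOM matrix from [tom()].
#' @param min_module_size Minimum genes per module; default 100.
#' @param deep_split Granularity knob in 0..4; maps linearly to the
#'   cut-height fraction of the merge-height range (0 -> 0.99, 4 -> 0.85).
#' @return Tibble (`gene_id`, `module`) with size-ranked color labels and
#'   the dendrogram attached as attribute `dendrogram`.
#' @export
cluster_and_cut <- function(tomm, min_module_size = 100, deep_split = 2) {
  stopifnot(deep_split >= 0, deep_split <= 4)
  genes <- rownames(tomm)
  if (nrow(tomm) < min_module_size) {
    return(tibble::tibble(gene_id = genes, module = "grey"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tomm), method = "average")
  # cut at a deep_split-dependent fraction of the dendrogram height range:
  # higher deep_split -> lower cut -> finer modules
  q <- 0.99 - 0.035 * deep_split
  cut_h <- min(hc$height) + q * (max(hc$height) - min(hc$height))
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- rep("grey", length(raw))
  if (length(keep) > 0) {
    keep <- keep[order(-sizes[keep])]
    pal <- module_palette(length(keep))
    for (i in seq_along(keep)) module[raw == as.integer(keep[i])] <- pal[i]
  }
  out <- tibble::tibble(gene_id = genes, module = module)
  attr(out, "dendrogram") <- hc
  out
}

#' Module eigengenes (first principal components)
#'
#' The eigengene of a module is the first right singular vector of the
#' module's standardized gene x sample block, scaled to unit variance and
#' sign-oriented so it correlates positively with the module's mean
#' expression profile.
#'
#' @param expr Expression tibble.
#' @param labels Tibble (`gene_id`, `module`); the "grey" label is skipped.
#' @return List: `me` (tibble `sample_id` + one column per module) and
#'   `var_explained` (tibble `module`, `var_explained`).
#' @export
module_eigengene <- function(expr, labels) {
  m <- as_expr_matrix(expr)
  mods <- setdiff(unique(labels$module), "grey")
  lab <- stats::setNames(labels$module, labels$gene_id)
  me <- list()
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    idx <- names(lab)[lab == mods[i]]
    G <- scale_rows(m[idx, , drop = FALSE])
    G[is.na(G)] <- 0  # masked cells at the gene mean after standardization
    sv <- svd(G)
    v1 <- sv$v[, 1]
    v1 <- as.numeric(scale(v1))
    if (stats::cor(v1, colMeans(G)) < 0) v1 <- -v1
    me[[mods[i]]] <- v1
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(
    me = dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)), tibble::as_tibble(me)),
    var_explained = tibble::tibble(module = mods, var_explained = ve)
  )
}

# module membership: correlation of each gene with each module eigengene
kme_matrix <- function(expr, mes) {
  m <- as_expr_matrix(expr)
  me_mat <- as.matrix(mes$me[setdiff(names(mes$me), "sample_id")])
  k <- stats::cor(t(m), me_mat, use = "pairwise.complete.obs")
  rownames(k) <- rownames(m)
  k
}

#' Apply eigengene-membership retention and module-core rules
#'
#' Genes whose correlation with their own module eigengene (kME) is below
#' `kme_keep` are reassigned to grey. A module is disbanded outright —
#' all members to grey — unless its "core" of at least
#' `ceiling(min_module_size / 3)` genes reaches kME `core_kme`.
#' Eigengenes are recomputed after reassignment.
#'
#' @param expr Expression tibble.
#' @param labels Tibble (`gene_id`, `module`).
#' @param mes Eigengenes from [module_eigengene()]; recomputed if `NULL`.
#' @param kme_keep Retention threshold; default 0.3.
#' @param core_kme Core membership threshold; default 0.5.
#' @param min_module_size Module size floor defining the core; default 100.
#' @return List: `labels` (updated tibble with `kme` column), `mes`
#'   (recomputed eigengenes), `disbanded` (character vector).
#' @export
apply_membership_rules <- function(expr, labels, mes = NULL, kme_keep = 0.3,
                                   core_kme = 0.5, min_module_size = 100) {
  if (is.null(mes)) mes <- module_eigengene(expr, labels)
  k <- kme_matrix(expr, mes)
  lab <- stats::setNames(labels$module, labels$gene_id)
  kme_own <- rep(NA_real_, length(lab))
  names(kme_own) <- names(lab)
  for (m in setdiff(unique(lab), "grey")) {
    idx <- names(lab)[lab == m]
    kme_own[idx] <- k[idx, m]
  }
  new_lab <- lab
  new_lab[!is.na(kme_own) & kme_own < kme_keep] <- "grey"
  core_n <- ceiling(min_module_size / 3)
  disbanded <- character(0)
  for (m in setdiff(unique(new_lab), "grey")) {
    idx <- names(new_lab)[new_lab == m]
    if (sum(kme_own[idx] >= core_kme, na.rm = TRUE) < core_n) {
      new_lab[idx] <- "grey"
      disbanded <- c(disbanded, m)
    }
  }
  out <- tibble::tibble(gene_id = names(new_lab), module = unname(new_lab),
                        kme = unname(kme_own))
  mes2 <- if (any(new_lab != "grey")) module_eigengene(expr, out) else
    list(me = tibble::tibble(sample_id = mes$me$sample_id),
         var_explained = tibble::tibble(module = character(), var_explained = numeric()))
  list(labels = out, mes = mes2, disbanded = disbanded)
}

#' Build a signed coexpression network with iterative grey removal
#'
#' One full round is: adjacency -> TOM -> average-linkage clustering with
#' a dynamic-height cut -> eigengenes -> membership rules. Genes landing
#' in the grey (unassigned) module are removed and the network is rebuilt
#' on the remainder, repeating until no gene is grey (or `max_iter`).
#'
#' @param expr Preprocessed expression tibble (no zero-variance genes).
#' @param power Soft-threshold power; use [pick_soft_threshold()] to
#'   choose it.
#' @param sign_mode `"signed"` (default) or `"unsigned"`.
#' @param min_module_size Minimum module size; default 100.
#' @param deep_split Tree-cut granularity 0..4; default 2.
#' @param kme_keep,core_kme Membership thresholds; defaults 0.3 / 0.5.
#' @param max_iter Maximum rebuild rounds; default 10.
#' @param keep_matrices Keep the final adjacency and TOM in the result?
#'   They are dense gene x gene matrices; default `FALSE`.
#' @return Object of class `coexpression_network`: `modules` tibble
#'   (`gene_id`, `module`, `kme`, `k_total`, `k_in`), `eigengenes`,
#'   `var_explained`, `kme` (gene x module membership matrix),
#'   `iterations`, `converged`, `power`, `sign_mode`, `params`, and
#'   optionally `adjacency` / `tom`.
#' @export
build_network <- function(expr, power, sign_mode = c("signed", "unsigned"),
                          min_module_size = 100, deep_split = 2,
                          kme_keep = 0.3, core_kme = 0.5, max_iter = 10,
                          keep_matrices = FALSE) {
  sign_mode <- match.arg(sign_mode)
  all_genes <- expr$gene_id
  active <- all_genes
  iterations <- list()
  converged <- FALSE
  final <- NULL
  A <- NULL
  for (it in seq_len(max_iter)) {
    sub <- expr[expr$gene_id %in% active, , drop = FALSE]
    if (nrow(sub) < min_module_size) {
      iterations[[it]] <- tibble::tibble(iteration = it, n_genes = nrow(sub),
                                         n_modules = 0L, n_grey = nrow(sub))
      active <- character(0)
      converged <- TRUE
      break
    }
    A <- adjacency_matrix(sub, power, sign_mode)
    W <- tom(A)
    labels <- cluster_and_cut(W, min_module_size = min_module_size,
                              deep_split = deep_split)
    if (all(labels$module == "grey")) {
      iterations[[it]] <- tibble::tibble(iteration = it, n_genes = nrow(sub),
                                         n_modules = 0L, n_grey = nrow(sub))
      active <- character(0)
      converged <- TRUE
      break
    }
    rules <- apply_membership_rules(sub, labels, kme_keep = kme_keep,
                                    core_kme = core_kme,
                                    min_module_size = min_module_size)
    n_grey <- sum(rules$labels$module == "grey")
    iterations[[it]] <- tibble::tibble(
      iteration = it, n_genes = nrow(sub),
      n_modules = length(setdiff(unique(rules$labels$module), "grey")),
      n_grey = n_grey
    )
    final <- list(labels = rules$labels, mes = rules$mes, A = A, W = W,
                  genes = sub$gene_id)
    if (n_grey == 0) {
      converged <- TRUE
      break
    }
    active <- rules$labels$gene_id[rules$labels$module != "grey"]
  }
  iterations <- dplyr::bind_rows(iterations)

  if (is.null(final) || length(active) == 0) {
    return(structure(list(
      modules = tibble::tibble(gene_id = character(), module = character(),
                               kme = numeric(), k_total = numeric(), k_in = numeric()),
      eigengenes = NULL, var_explained = NULL, kme = NULL,
      iterations = iterations, converged = converged,
      power = power, sign_mode = sign_mode,
      params = list(min_module_size = min_module_size, deep_split = deep_split,
                    kme_keep = kme_keep, core_kme = core_kme),
      n_dropped = length(all_genes)
    ), class = "coexpression_network"))
  }

  keep_genes <- final$labels$gene_id[final$labels$module != "grey"]
  if (!identical(sort(keep_genes), sort(final$genes))) {
    # non-converged exit: restrict the last matrices to the assigned genes
    sub <- expr[expr$gene_id %in% keep_genes, , drop = FALSE]
    final$A <- adjacency_matrix(sub, power, sign_mode)
    final$W <- tom(final$A)
    final$labels <- final$labels[final$labels$module != "grey", ]
    final$mes <- module_eigengene(sub, final$labels)
    final$genes <- keep_genes
  }

  # relabel modules by size rank with the conventional palette
  labels <- final$labels[final$labels$module != "grey", ]
  sizes <- sort(table(labels$module), decreasing = TRUE)
  pal <- module_palette(length(sizes))
  remap <- stats::setNames(pal, names(sizes))
  labels$module <- unname(remap[labels$module])
  sub <- expr[expr$gene_id %in% labels$gene_id, , drop = FALSE]
  mes <- module_eigengene(sub, labels)
  kme_full <- kme_matrix(sub, mes)
  ord <- match(labels$gene_id, rownames(final$A))
  conn <- connectivity(final$A[ord, ord, drop = FALSE], labels)
  labels$kme <- kme_full[cbind(labels$gene_id, labels$module)]
  modules <- dplyr::left_join(labels, conn, by = "gene_id")

  structure(list(
    modules = modules,
    eigengenes = mes$me,
    var_explained = mes$var_explained,
    kme = kme_full,
    iterations = iterations,
    converged = converged,
    power = power,
    sign_mode = sign_mode,
    params = list(min_module_size = min_module_size, deep_split = deep_split,
                  kme_keep = kme_keep, core_kme = core_kme),
    n_dropped = length(all_genes) - nrow(modules),
    adjacency = if (keep_matrices) final$A[ord, ord, drop = FALSE],
    tom = if (keep_matrices) final$W[ord, ord, drop = FALSE]
  ), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("%s coexpression network: %d genes in %d modules (power %s)\n",
              if (x$sign_mode == "signed") "Signed" else "Unsigned",
              nrow(x$modules),
              length(setdiff(unique(x$modules$module), "grey")), format(x$power)))
  if (nrow(x$modules) > 0) {
    print(dplyr::count(x$modules, .data$module, sort = TRUE), n = 25)
  }
  cat("converged:", x$converged, "after", nrow(x$iterations), "iteration(s);",
      x$n_dropped, "gene(s) dropped as grey\n")
  invisible(x)
}

#' @exportS3Method
tidy.coexpression_network <- function(x, ...) x$modules

#' @exportS3Method
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$modules),
    n_modules = length(setdiff(unique(x$modules$module), "grey")),
    n_dropped = x$n_dropped,
    power = x$power,
    sign_mode = x$sign_mode,
    iterations = nrow(x$iterations),
    converged = x$converged,
    mean_var_explained = if (!is.null(x$var_explained)) mean(x$var_explained$var_explained) else NA_real_
  )
}

#' Export the TOM as a weighted edge list
#'
#' @param tomm TOM (or any symmetric weight) matrix.
#' @return Tibble `gene_i`, `gene_j`, `weight` over the upper triangle.
#' @export
tom_edge_list <- function(tomm) {
  idx <- which(upper.tri(tomm), arr.ind = TRUE)
  tibble::tibble(
    gene_i = rownames(tomm)[idx[, 1]],
    gene_j = colnames(tomm)[idx[, 2]],
    weight = tomm[idx]
  )
}
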