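#' Singing-induced variability effect size
#'
#' Normalized contrast `(NS - UD) / (NS + UD)` between a song feature's
#' value (typically the coefficient of variation) after two hours of
#' non-singing (NS) versus two hours of undirected singing (UD). Negative
#' values indicate increased song variability after UD singing; the
#' transformation weights a fixed change more heavily for features with
#' smaller baseline values.
#'
#' @param ns,ud Feature values after non-singing / undirected singing
#'   (vectorized).
#' @return `(ns - ud) / (ns + ud)`, in (-1, 1) for positive inputs.
#' @export
#' @examples
#' effect_size(100, 150)  # -0.2
effect_size <- function(ns, ud) {
  if (any(ns + ud == 0)) stop("ns + ud must be nonzero", call. = FALSE)
  (ns - ud) / (ns + ud)
}

#' Motif identity score
#'
#' The product of percentage similarity and percentage accuracy divided by
#' 100, giving a 0-100 score; higher identity indicates lower motif-level
#' variability.
#'
#' @param similarity_pct,accuracy_pct Percentages in \[0, 100\]
#'   (vectorized).
#' @return `similarity_pct * accuracy_pct / 100`.
#' @export
motif_identity <- function(similarity_pct, accuracy_pct) {
  if (any(similarity_pct < 0 | similarity_pct > 100) ||
      any(accuracy_pct < 0 | accuracy_pct > 100)) {
    stop("inputs must lie in [0, 100]", call. = FALSE)
  }
  similarity_pct * accuracy_pct / 100
}

#' Gene significance: gene-trait Pearson correlations
#'
#' The signed Pearson correlation between each gene's expression profile
#' and each behavioral trait, over pairwise-complete samples.
#'
#' @param expr Expression tibble (`gene_id` plus samples).
#' @param traits Trait tibble (`sample_id` plus numeric trait columns);
#'   rows are matched to expression samples by `sample_id`.
#' @return Tibble: `gene_id` plus one correlation column per trait.
#' @export
gene_significance <- function(expr, traits) {
  m <- as_expr_matrix(expr)
  stopifnot("sample_id" %in% names(traits))
  tr <- traits[match(colnames(m), traits$sample_id), , drop = FALSE]
  if (anyNA(tr$sample_id)) stop("traits missing for some samples", call. = FALSE)
  tm <- as.matrix(tr[setdiff(names(tr), "sample_id")])
  const <- apply(tm, 2, function(x) stats::sd(x, na.rm = TRUE)) == 0
  if (any(const, na.rm = TRUE)) {
    warning("constant trait(s): ", paste(colnames(tm)[const], collapse = ", "),
            "; correlations set to NA")
  }
  gs <- suppressWarnings(stats::cor(t(m), tm, use = "pairwise.complete.obs"))
  gs[, which(const)] <- NA_real_
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(gs))
}

# two-sided p-value for a Pearson correlation
cor_p_value <- function(r, n, method = c("fisher", "student")) {
  method <- match.arg(method)
  r <- pmin(1, pmax(-1, r))
  if (method == "fisher") {
    z <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, r))) * sqrt(n - 3)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  p[abs(r) == 1] <- 0
  p
}

#' Benjamini-Hochberg adjustment over a fixed hypothesis count
#'
#' Step-up FDR adjustment treating the family as exactly `m` hypotheses
#' (the module-trait analysis uses m = traits x modules even when fewer
#' p-values are supplied; missing ones count as p = 1).
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @param m Total hypotheses; must be >= `length(pvals)`.
#' @return Adjusted q-values, monotone in and never below the raw p.
#' @export
fdr_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(pvals)) stop("m must be >= number of supplied p-values", call. = FALSE)
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Module-trait correlation with Fisher-transform p-values
#'
#' Pearson correlation between every module eigengene and every
#' behavioral trait, with a two-sided p-value from the Fisher z
#' transform, \eqn{z = \mathrm{atanh}(\rho)\sqrt{n-3}} against the
#' standard normal (`method = "student"` gives the t-distribution form
#' instead). Q-values are BH-adjusted over all module x trait tests; the
#' `pass_fdr` flag marks q <= `fdr_level`.
#'
#' @param mes Eigengene tibble (`sample_id` plus one column per module),
#'   e.g. `net$eigengenes`.
#' @param traits Trait tibble (`sample_id` plus trait columns).
#' @param method `"fisher"` (default) or `"student"`.
#' @param fdr_level FDR pass threshold; default 0.05.
#' @return Tibble: `module`, `trait`, `rho`, `p`, `q`, `pass_fdr`, `n`.
#' @export
module_trait_correlation <- function(mes, traits, method = c("fisher", "student"),
                                     fdr_level = 0.05) {
  method <- match.arg(method)
  stopifnot("sample_id" %in% names(mes), "sample_id" %in% names(traits))
  tr <- traits[match(mes$sample_id, traits$sample_id), , drop = FALSE]
  if (anyNA(tr$sample_id)) stop("traits missing for some samples", call. = FALSE)
  me_mat <- as.matrix(mes[setdiff(names(mes), "sample_id")])
  tr_mat <- as.matrix(tr[setdiff(names(tr), "sample_id")])
  n <- nrow(me_mat)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  rho <- suppressWarnings(stats::cor(me_mat, tr_mat, use = "pairwise.complete.obs"))
  out <- tibble::tibble(
    module = rep(rownames(rho), times = ncol(rho)),
    trait = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho)
  )
  out$p <- cor_p_value(out$rho, n, method)
  out$q <- fdr_adjust(out$p, m = nrow(out))
  out$pass_fdr <- out$q <= fdr_level
  out$n <- n
  tibble::as_tibble(out)
}

#' Heatmap of module-trait correlations
#'
#' Mirrors the conventional signed two-color display: tiles colored by
#' rho, annotated with rho and the uncorrected p-value, FDR-passing cells
#' outlined.
#'
#' @param mt Result of [module_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait_heatmap <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$trait, y = .data$module, fill = .data$rho)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_tile(data = dplyr::filter(mt, .data$pass_fdr),
                       fill = NA, color = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.3g)", .data$rho, .data$p)), size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "#3B4CC0", mid = "white", high = "#B40426",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho",
                  title = "Module eigengene - trait correlations") +
    ggplot2::theme_minimal()
}
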