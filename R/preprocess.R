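#' Convert read counts to transcripts per million (TPM)
#'
#' Within each sample, counts are divided by gene length to give a read
#' rate, and rates are rescaled so each sample sums to 10^6:
#' \eqn{TPM_i = 10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)}.
#'
#' @param counts Count tibble (`gene_id` plus one column per sample).
#' @param gene_lengths Tibble (`gene_id`, `length`) or named vector of
#'   positive gene lengths in base pairs.
#' @return TPM expression tibble; every column sums to 10^6.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  m <- as_expr_matrix(counts)
  len <- if (is.data.frame(gene_lengths)) {
    stats::setNames(gene_lengths$length, gene_lengths$gene_id)[rownames(m)]
  } else {
    gene_lengths[rownames(m)]
  }
  if (anyNA(len) || any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  as_expr_tibble(sweep(rate, 2, tot, "/") * 1e6)
}

#' Log2-transform expression and drop zero-variance genes
#'
#' Applies `log2(x + pseudocount)` and removes genes with zero variance
#' across samples. The number of removed genes is attached as attribute
#' `genes_removed_zero_variance`.
#'
#' @param expr Expression tibble with non-negative values (e.g. TPM).
#' @param pseudocount Added before the log; default 1. With
#'   `pseudocount = 0`, zero values are an error under the default
#'   `zero_policy = "error"`; `"allow"` yields `-Inf` instead.
#' @param zero_policy `"error"` or `"allow"`; see above.
#' @return Log2 expression tibble.
#' @export
log_transform <- function(expr, pseudocount = 1, zero_policy = c("error", "allow")) {
  zero_policy <- match.arg(zero_policy)
  m <- as_expr_matrix(expr)
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values", call. = FALSE)
  if (pseudocount == 0 && zero_policy == "error" && any(m == 0, na.rm = TRUE)) {
    stop("zero values with pseudocount = 0; set zero_policy = 'allow' or use a pseudocount",
         call. = FALSE)
  }
  lm2 <- log2(m + pseudocount)
  v <- apply(lm2, 1, stats::var, na.rm = TRUE)
  # constant genes out; genes with infinite spread (a -Inf under
  # zero_policy = "allow") are not zero-variance and are kept
  keep <- is.nan(v) | (!is.na(v) & v > 0)
  out <- as_expr_tibble(lm2[keep, , drop = FALSE])
  attr(out, "genes_removed_zero_variance") <- sum(!keep)
  out
}

#' Iteratively mask single-sample expression outliers
#'
#' Per gene, any cell more than `sd_cutoff` sample standard deviations
#' from the gene's mean (both computed over currently unmasked cells) is
#' masked (`NA`), and the pass repeats until a full pass masks nothing.
#' Genes left with fewer than `min_unmasked` cells are dropped with a
#' warning.
#'
#' @param expr Expression tibble.
#' @param sd_cutoff Masking threshold in SD units; default 2.5. The
#'   inequality is strict: exactly `sd_cutoff` SD is retained.
#' @param min_unmasked Minimum unmasked cells per gene; default 3.
#' @return List: `expr` (masked tibble) and `report` (list with
#'   `cells_masked_per_iteration`, `genes_dropped`, `parameters`).
#' @export
iterative_outlier_mask <- function(expr, sd_cutoff = 2.5, min_unmasked = 3) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 4) stop("need >= 4 samples for outlier masking", call. = FALSE)
  masked_per_iter <- integer(0)
  repeat {
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1, stats::sd, na.rm = TRUE)
    dev <- abs(m - mu)
    hit <- !is.na(m) & !is.na(sd) & sd > 0 & dev > sd_cutoff * sd
    masked_per_iter <- c(masked_per_iter, sum(hit))
    if (!any(hit)) break
    m[hit] <- NA
  }
  n_ok <- rowSums(!is.na(m))
  drop <- n_ok < min_unmasked
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped with < ", min_unmasked,
            " unmasked samples after outlier masking")
    m <- m[!drop, , drop = FALSE]
  }
  list(
    expr = as_expr_tibble(m),
    report = list(
      cells_masked_per_iteration = masked_per_iter,
      genes_dropped = sum(drop),
      parameters = list(sd_cutoff = sd_cutoff, min_unmasked = min_unmasked)
    )
  )
}

#' Remove samples with low intrasample correlation (ISC)
#'
#' A sample's ISC is the mean Pearson correlation of its expression vector
#' with every other sample (pairwise-complete over masked cells;
#' configurable to the median). Samples with ISC strictly below the group
#' mean minus `sd_cutoff` group SDs are removed.
#'
#' @param expr Expression tibble.
#' @param sd_cutoff Hard cutoff in SD units; default 2.
#' @param summary `"mean"` (default) or `"median"` aggregation over the
#'   pairwise correlations.
#' @return List: `expr` (filtered tibble) and `report` (list with `isc`
#'   tibble, `samples_removed`, `parameters`).
#' @export
filter_samples_by_isc <- function(expr, sd_cutoff = 2, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  m <- as_expr_matrix(expr)
  if (ncol(m) < 3) stop("need >= 3 samples for the ISC filter", call. = FALSE)
  cc <- stats::cor(m, use = "pairwise.complete.obs")
  diag(cc) <- NA
  agg <- if (summary == "mean") function(x) mean(x, na.rm = TRUE) else
    function(x) stats::median(x, na.rm = TRUE)
  isc <- apply(cc, 2, agg)
  cut <- mean(isc) - sd_cutoff * stats::sd(isc)
  drop <- isc < cut  # strict: exactly at the cutoff is retained
  if (sum(!drop) < 3) stop("fewer than 3 samples would remain after ISC filter", call. = FALSE)
  list(
    expr = as_expr_tibble(m[, !drop, drop = FALSE]),
    report = list(
      isc = tibble::tibble(sample_id = colnames(m), isc = unname(isc), removed = unname(drop)),
      samples_removed = colnames(m)[drop],
      parameters = list(sd_cutoff = sd_cutoff, summary = summary)
    )
  )
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample to share the same empirical distribution: the
#' across-sample mean of sorted values. Ties receive the mean of their
#' tied ranks. Masked cells are first imputed to the gene's unmasked mean
#' (quantile normalization needs complete columns; mean imputation is
#' correlation-neutral).
#'
#' @param expr Expression tibble, possibly with masked (`NA`) cells.
#' @return Quantile-normalized expression tibble (no masked cells).
#' @export
quantile_normalize <- function(expr) {
  m <- as_expr_matrix(expr)
  if (anyNA(m)) {
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 1]]
  }
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(q) <- dimnames(m)
  as_expr_tibble(q)
}

#' Full expression preprocessing pipeline
#'
#' Runs the fixed stage order: TPM -> log2 -> zero-variance removal ->
#' iterative outlier masking -> ISC sample filter -> quantile
#' normalization, and collects a per-stage report.
#'
#' @param counts Count tibble (`gene_id` plus samples).
#' @param gene_lengths Gene lengths (tibble or named vector).
#' @param pseudocount Log2 pseudocount; default 1.
#' @param outlier_sd Outlier masking cutoff in SDs; default 2.5.
#' @param isc_sd ISC sample cutoff in SDs; default 2.
#' @return Object of class `preprocess_result`: list with `expr` (final
#'   expression tibble) and `report`.
#' @export
preprocess_expression <- function(counts, gene_lengths, pseudocount = 1,
                                  outlier_sd = 2.5, isc_sd = 2) {
  tpm <- counts_to_tpm(counts, gene_lengths)
  lg <- log_transform(tpm, pseudocount = pseudocount)
  om <- iterative_outlier_mask(lg, sd_cutoff = outlier_sd)
  sf <- filter_samples_by_isc(om$expr, sd_cutoff = isc_sd)
  qn <- quantile_normalize(sf$expr)
  structure(list(
    expr = qn,
    report = list(
      genes_in = nrow(counts),
      genes_removed_zero_variance = attr(lg, "genes_removed_zero_variance"),
      outlier_masking = om$report,
      isc_filter = sf$report,
      genes_out = nrow(qn),
      samples_out = ncol(qn) - 1L,
      parameters = list(pseudocount = pseudocount, outlier_sd = outlier_sd,
                        isc_sd = isc_sd)
    )
  ), class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  r <- x$report
  cat("Preprocessed expression: ", r$genes_out, " genes x ", r$samples_out,
      " samples\n", sep = "")
  cat("  zero-variance genes removed: ", r$genes_removed_zero_variance, "\n", sep = "")
  cat("  outlier cells masked per pass: ",
      paste(r$outlier_masking$cells_masked_per_iteration, collapse = ", "), "\n", sep = "")
  cat("  samples removed by ISC: ",
      if (length(r$isc_filter$samples_removed)) paste(r$isc_filter$samples_removed, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
glance.preprocess_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    genes_in = r$genes_in,
    genes_removed_zero_variance = r$genes_removed_zero_variance,
    genes_dropped_outlier = r$outlier_masking$genes_dropped,
    samples_removed_isc = length(r$isc_filter$samples_removed),
    masking_passes = length(r$outlier_masking$cells_masked_per_iteration),
    genes_out = r$genes_out,
    samples_out = r$samples_out
  )
}
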