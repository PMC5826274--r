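#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Module label palette, ordered by module size rank; "grey" is reserved for
# unassigned genes and never appears here.
module_palette <- function(n) {
  pal <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
  )
  if (n <= length(pal)) pal[seq_len(n)] else c(pal, paste0("module", seq_len(n - length(pal))))
}

#' Convert an expression tibble to a gene x sample matrix
#'
#' Expression tables in songnet are tibbles whose first column (`gene_id`)
#' holds unique gene identifiers and whose remaining columns are samples.
#' Masked cells are `NA`.
#'
#' @param expr Expression tibble (`gene_id` plus one numeric column per
#'   sample).
#' @return Numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
as_expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  if (anyDuplicated(expr$gene_id) > 0) {
    stop("duplicate gene identifiers in expression table", call. = FALSE)
  }
  samp <- setdiff(names(expr), "gene_id")
  if (anyDuplicated(samp) > 0) stop("duplicate sample identifiers", call. = FALSE)
  m <- as.matrix(expr[samp])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Convert a gene x sample matrix to an expression tibble
#'
#' @param m Numeric matrix with rownames (genes) and colnames (samples).
#' @return Tibble with a `gene_id` column followed by sample columns.
#' @export
as_expr_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

# standardize rows (genes) to mean 0, sd 1 over unmasked samples
scale_rows <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  if (any(sd == 0 | is.na(sd))) {
    stop("zero-variance gene encountered; filter upstream", call. = FALSE)
  }
  (m - mu) / sd
}

# deterministic sub-seed for a named pipeline stage, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
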