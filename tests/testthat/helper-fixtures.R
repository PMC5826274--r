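# Small fixture builders shared across test files. Everything is
# generated in code; no binary fixtures.

# expression tibble from a bare matrix, auto-labelling genes/samples
expr_fixture <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  songnet::as_expr_tibble(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small planted-module design used by several network tests
small_synth <- function(n_samples = 60, sizes = c(80, 60, 50),
                        background = 60, kme = 0.9, seed = 1, ...) {
  songnet::synth_config(
    n_samples = n_samples, module_sizes = sizes,
    n_background_genes = background, kme_targets = kme, seed = seed, ...
  )
}

# brute-force topological overlap by triple loop (independent oracle)
tom_brute_force <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  W <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      W[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  dimnames(W) <- dimnames(A)
  W
}

# random valid adjacency matrix (symmetric, diag 1, entries in [0, 1])
random_adjacency <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

# a vector with an exact sample correlation `r` to x (Gram-Schmidt)
vector_with_exact_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(length(x))
  zx <- stats::residuals(stats::lm(z ~ x))
  xs <- as.numeric(scale(x))
  zs <- as.numeric(scale(zx))
  r * xs + sqrt(1 - r^2) * zs
}

adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)
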