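# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: eigendecomposition for the GNM pseudoinverse,
# exhaustive pair counting for AUROC, the classical d^2 formula for
# Spearman, and sort-and-slice for top-k extraction.

# GNM B-factors by explicit eigendecomposition, dropping zero modes.
oracle_gnm_bfactor <- function(gamma, scale = 1, tol = 1e-9) {
  e <- eigen(gamma, symmetric = TRUE)
  keep <- e$values > tol
  v <- e$vectors[, keep, drop = FALSE]
  ginv_diag <- rowSums(sweep(v^2, 2L, e$values[keep], "/"))
  scale * ginv_diag
}

# AUROC by brute force over all positive/negative pairs, ties = 1/2.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Spearman via the printed d^2 formula (valid only without ties).
oracle_srcc_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Top-k selection by exhaustive sort-and-slice, ties to lower MHC index.
oracle_topk <- function(E, k, candidates) {
  lapply(seq_len(ncol(E)), function(j) {
    cand <- which(candidates[, j] > 0)
    if (!length(cand)) return(integer(0))
    ord <- cand[order(-E[cand, j], cand)]
    head(ord, k)
  })
}

# Random connected 0/1 adjacency (spanning tree plus random extra edges).
random_connected_adj <- function(n, extra = n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)[-1L]) {
    j <- sample.int(i - 1L, 1L)
    A[i, j] <- A[j, i] <- 1
  }
  for (e in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    A[ij[1L], ij[2L]] <- A[ij[2L], ij[1L]] <- 1
  }
  diag(A) <- 0
  A
}

# Tiny in-memory dataset for fast end-to-end tests.
tiny_dataset <- function(n_alleles = 3, n_peptides = 8, mhc_length = 30,
                         seed = 42, ...) {
  make_dataset(synthetic_config(n_alleles = n_alleles,
                                n_peptides = n_peptides,
                                mhc_length = mhc_length,
                                n_pseudo_positions = 8,
                                seed = seed, ...))
}

tiny_train_config <- function(epochs = 2, seed = 7, ...) {
  cmhs_small_config(list(train = list(epochs = epochs), seed = seed, ...))
}
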