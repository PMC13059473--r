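#' Encoded sequence container
#'
#' Per-residue feature matrix (embedder block then BLOSUM block) with a
#' mask marking real (non-pad) positions.
#' @param features length x width numeric matrix
#' @param mask logical/0-1 vector, one entry per row
#' @param role "MHC" or "peptide"
#' @export
encoded_sequence <- function(features, mask, role = c("MHC", "peptide")) {
  role <- match.arg(role)
  features <- as.matrix(features)
  if (length(mask) != nrow(features)) {
    cmhs_stop("mask length must equal feature rows", "cmhs_dimension_error")
  }
  structure(list(features = features, mask = as.integer(mask != 0),
                 role = role), class = "cmhs_encseq")
}

#' Concatenate embedder and BLOSUM feature blocks
#'
#' Column order is embedder block first, BLOSUM block second (the fixed
#' layout used throughout the package). The pad mask is derived from the
#' BLOSUM block (pad rows are all-zero there by construction) unless given.
#'
#' @param blosum_block length x 20 matrix from [blosum50_encode()]
#' @param embed_block length x e matrix from [embed_sequence()]
#' @param role "MHC" or "peptide"
#' @param mask optional explicit pad mask
#' @return [encoded_sequence()] of width `e + 20`
#' @export
concat_features <- function(blosum_block, embed_block,
                            role = c("MHC", "peptide"), mask = NULL) {
  role <- match.arg(role)
  if (nrow(blosum_block) != nrow(embed_block)) {
    cmhs_stop("feature blocks must have equal row counts",
              "cmhs_dimension_error")
  }
  if (is.null(mask)) mask <- rowSums(abs(blosum_block)) > 0
  encoded_sequence(cbind(embed_block, blosum_block), mask, role)
}

# ---- LoRA ------------------------------------------------------------------

#' Low-rank adapter for an attention projection
#'
#' The adapted weight is `W + B %*% t(A)`, a rank-<= r update; only A and B
#' are trainable while the base projection stays frozen.
#' @param A d_b x r matrix
#' @param B d_a x r matrix
#' @param target which projection this adapter updates ("Q", "K" or "V")
#' @export
lora_adapter <- function(A, B, target = c("Q", "K", "V")) {
  target <- match.arg(target)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    cmhs_stop("A and B must share the rank dimension", "cmhs_dimension_error")
  }
  structure(list(A = A, B = B, r = ncol(A), target = target),
            class = "cmhs_lora")
}

#' Zero-initialized adapter (identity update at start of fine-tuning)
#' @param d_a,d_b dimensions of the base weight (d_a x d_b)
#' @param r adapter rank
#' @param target projection name
#' @param seed seed for the B initialization (A starts at zero, the
#'   standard LoRA init, so the initial update is exactly zero)
#' @export
lora_init <- function(d_a, d_b, r, target = c("Q", "K", "V"), seed = 1L) {
  target <- match.arg(target)
  B <- with_seed(derive_seed(seed, paste0("loraB", target)),
                 matrix(stats::rnorm(d_a * r, sd = 1 / sqrt(r)), d_a, r))
  lora_adapter(A = matrix(0, d_b, r), B = B, target = target)
}

#' Apply a low-rank update to a base weight matrix
#' @param W d_a x d_b base weight (never mutated)
#' @param adapter [lora_adapter()]
#' @return `W + B %*% t(A)`
#' @export
lora_update <- function(W, adapter) {
  W <- as.matrix(W)
  if (nrow(adapter$B) != nrow(W) || nrow(adapter$A) != ncol(W)) {
    cmhs_stop(sprintf(
      "adapter shape (B %dx%d, A %dx%d) does not conform to W %dx%d",
      nrow(adapter$B), ncol(adapter$B), nrow(adapter$A), ncol(adapter$A),
      nrow(W), ncol(W)), "cmhs_dimension_error")
  }
  W + adapter$B %*% t(adapter$A)
}

#' Q/K/V projections with low-rank-adapted weights
#'
#' @param M length x width input matrix
#' @param base_weights named list with frozen `Q`, `K`, `V` matrices
#' @param adapters named list of [lora_adapter()]s (one per projection), or
#'   NULL for the frozen path
#' @return list with adapted `Q`, `K`, `V` projection outputs
#' @export
adapted_attention <- function(M, base_weights, adapters = NULL) {
  M <- as.matrix(M)
  out <- list()
  for (proj in c("Q", "K", "V")) {
    W <- base_weights[[proj]]
    if (is.null(W)) cmhs_stop(sprintf("missing base weight %s", proj),
                              "cmhs_config_error")
    if (is.null(adapters)) {
      out[[proj]] <- M %*% W
    } else {
      ad <- adapters[[proj]]
      if (is.null(ad)) cmhs_stop(
        sprintf("missing adapter for projection %s", proj),
        "cmhs_config_error")
      out[[proj]] <- M %*% lora_update(W, ad)
    }
  }
  out
}

# ---- embedders -------------------------------------------------------------

#' Deterministic stub embedder (seeded random projection of one-hots)
#'
#' The default test-time stand-in for a protein language model: each
#' residue's one-hot vector is projected to width `e` by a fixed seeded
#' Gaussian matrix. Deterministic, frozen, no adapter support.
#' @param width output width e
#' @param seed projection seed (part of the embedder identity, not the run
#'   seed: the same embedder must embed identically across runs)
#' @export
embedder_stub <- function(width = 320L, seed = 42L) {
  P <- with_seed(derive_seed(seed, "stub_proj"),
                 matrix(stats::rnorm(20L * width, sd = 1), 20L, width))
  structure(list(kind = "stub", width = as.integer(width),
                 deterministic = TRUE, supports_adapters = FALSE, P = P),
            class = "cmhs_embedder")
}

#' Tiny built-in single-layer attention encoder
#'
#' A one-head self-attention layer over seeded frozen token + sinusoidal
#' position embeddings, with optional low-rank adapters on the Q/K/V
#' projections — small enough to run on a laptop yet exercising the same
#' adapter math as a full protein language model.
#' @param width model width (default 32)
#' @param seed embedder identity seed
#' @export
embedder_tiny_attention <- function(width = 32L, seed = 42L) {
  width <- as.integer(width)
  mk <- function(tag, n, m, sd) with_seed(derive_seed(seed, tag),
                  matrix(stats::rnorm(n * m, sd = sd), n, m))
  structure(list(kind = "tiny_attention", width = width,
                 deterministic = TRUE, supports_adapters = TRUE,
                 E = mk("tok", 20L, width, 1),
                 W = list(Q = mk("Wq", width, width, 1 / sqrt(width)),
                          K = mk("Wk", width, width, 1 / sqrt(width)),
                          V = mk("Wv", width, width, 1 / sqrt(width)))),
            class = "cmhs_embedder")
}

.posenc <- function(n, width) {
  pos <- seq_len(n) - 1L
  i <- seq_len(width) - 1L
  angle <- outer(pos, 1 / (10000^((i %/% 2L) * 2 / width)))
  out <- angle
  even <- (i %% 2L) == 0L
  out[, even] <- sin(angle[, even, drop = FALSE])
  out[, !even] <- cos(angle[, !even, drop = FALSE])
  out
}

#' Embed a sequence with a pluggable embedder
#'
#' @param seq amino-acid string
#' @param embedder [embedder_stub()] or [embedder_tiny_attention()]
#' @param adapters optional named list of Q/K/V [lora_adapter()]s; only
#'   legal for embedders with `supports_adapters`
#' @param target_length pad the output with zero rows up to this length
#' @return target_length x width matrix
#' @export
embed_sequence <- function(seq, embedder, adapters = NULL,
                           target_length = nchar(seq)) {
  stopifnot(inherits(embedder, "cmhs_embedder"))
  if (!is.null(adapters) && !embedder$supports_adapters) {
    cmhs_stop(sprintf("embedder '%s' does not support adapters",
                      embedder$kind), "cmhs_config_error")
  }
  seq <- toupper(seq)
  letters <- strsplit(seq, "")[[1L]]
  idx <- match(letters, AA_ALPHABET)
  if (anyNA(idx)) {
    cmhs_stop(sprintf("unknown residue '%s' at position %d",
                      letters[which(is.na(idx))[1L]], which(is.na(idx))[1L]),
              "cmhs_encoding_error")
  }
  n <- length(idx)
  emb <- if (embedder$kind == "stub") {
    embedder$P[idx, , drop = FALSE]
  } else {
    X <- embedder$E[idx, , drop = FALSE] + .posenc(n, embedder$width)
    qkv <- adapted_attention(X, embedder$W, adapters)
    att <- qkv$Q %*% t(qkv$K) / sqrt(embedder$width)
    att <- exp(att - apply(att, 1L, max))
    att <- att / rowSums(att)
    X + att %*% qkv$V
  }
  if (target_length > n) {
    emb <- rbind(emb, matrix(0, target_length - n, embedder$width))
  }
  emb
}

# ---- learnable embedding noise --------------------------------------------

#' Trainable Gaussian noise specification for embedding features
#'
#' Per-feature mean and log standard deviation (`sigma = exp(log_sigma)`
#' is positive by construction). Defaults: zero mean, sigma 0.05.
#' @param width feature width
#' @param mu mean vector (recycled)
#' @param log_sigma log-sd vector (recycled)
#' @param enabled logical switch
#' @export
noise_spec <- function(width, mu = 0, log_sigma = log(0.05), enabled = TRUE) {
  structure(list(mu = rep_len(mu, width),
                 log_sigma = rep_len(log_sigma, width),
                 enabled = isTRUE(enabled)),
            class = "cmhs_noise")
}

#' Inject learnable Gaussian noise into embedding features
#'
#' Training mode adds an independent draw `eps ~ N(mu, sigma^2)` per
#' position and feature; inference mode (and `enabled = FALSE`) is the
#' identity map.
#' @param X length x width feature matrix
#' @param spec [noise_spec()]
#' @param seed integer seed
#' @param training logical
#' @export
apply_embedding_noise <- function(X, spec, seed = 1L, training = TRUE) {
  X <- as.matrix(X)
  if (!training || !spec$enabled) return(X)
  stopifnot(ncol(X) == length(spec$mu))
  sigma <- exp(spec$log_sigma)
  eps <- with_seed(seed, matrix(stats::rnorm(length(X)), nrow(X)) *
                           matrix(sigma, nrow(X), ncol(X), byrow = TRUE) +
                           matrix(spec$mu, nrow(X), ncol(X), byrow = TRUE))
  X + eps
}

# ---- multi-level CNN feature pyramid ---------------------------------------

#' Initialize feature-pyramid CNN parameters
#'
#' Two 1-D convolution layers for the MHC track (kernel 5 by default) and
#' one for the peptide track (kernel 3), He-initialized. When `channels`
#' is NULL it defaults to the input width so that all three pyramid levels
#' share one per-level width.
#' @param input_width width of the encoded features (e + 20)
#' @param channels convolution channels (NULL = input width)
#' @param kernel_m,kernel_p odd kernel sizes for MHC / peptide tracks
#' @param seed init seed
#' @export
pyramid_params <- function(input_width, channels = NULL, kernel_m = 5L,
                           kernel_p = 3L, seed = 1L) {
  channels <- as.integer(channels %||% input_width)
  he <- function(tag, fanin, cout) with_seed(derive_seed(seed, tag),
          matrix(stats::rnorm(fanin * cout, sd = sqrt(2 / fanin)),
                 fanin, cout))
  list(
    W1m = he("W1m", kernel_m * input_width, channels),
    b1m = matrix(0, 1L, channels),
    W2m = he("W2m", kernel_m * channels, channels),
    b2m = matrix(0, 1L, channels),
    W1p = he("W1p", kernel_p * input_width, channels),
    b1p = matrix(0, 1L, channels),
    kernel_m = as.integer(kernel_m), kernel_p = as.integer(kernel_p),
    channels = channels
  )
}

# Autodiff core of the pyramid; params entries may be constants or
# ad_param nodes. Returns a 1 x (2*input_width + 4*channels) node.
.pyramid_forward <- function(Xm, Xp, mask_m, mask_p, pn, kernel_m, kernel_p) {
  l0 <- ad_cbind(ad_maxpool_masked(Xm, mask_m),
                 ad_maxpool_masked(Xp, mask_p))
  c1m <- ad_relu(ad_conv1d(Xm, pn$W1m, pn$b1m, kernel_m))
  c1p <- ad_relu(ad_conv1d(Xp, pn$W1p, pn$b1p, kernel_p))
  l1 <- ad_cbind(ad_maxpool_masked(c1m, mask_m),
                 ad_maxpool_masked(c1p, mask_p))
  c2m <- ad_relu(ad_conv1d(c1m, pn$W2m, pn$b2m, kernel_m))
  l2 <- ad_cbind(ad_maxpool_masked(c2m, mask_m),
                 ad_maxpool_masked(c1p, mask_p))
  ad_cbind(l0, l1, l2)
}

#' Multi-level sequence feature pyramid
#'
#' Level 0 pools the raw encoded MHC and peptide features; level 1 pools
#' the first CNN layer of each track; level 2 pools the second MHC CNN
#' layer together with the peptide CNN layer. Pooling is a global masked
#' max per channel, so the output width depends only on the configuration,
#' never on sequence length: `2 * input_width + 4 * channels`.
#'
#' @param X_M,X_P [encoded_sequence()] objects (peptide already
#'   noise-injected when training)
#' @param params [pyramid_params()]
#' @return numeric vector `S_final`
#' @export
feature_pyramid <- function(X_M, X_P, params) {
  stopifnot(inherits(X_M, "cmhs_encseq"), inherits(X_P, "cmhs_encseq"))
  ad_tape_reset()
  pn <- list(W1m = ad_const(params$W1m), b1m = ad_const(params$b1m),
             W2m = ad_const(params$W2m), b2m = ad_const(params$b2m),
             W1p = ad_const(params$W1p), b1p = ad_const(params$b1p))
  node <- .pyramid_forward(ad_const(X_M$features), ad_const(X_P$features),
                           X_M$mask, X_P$mask, pn,
                           params$kernel_m, params$kernel_p)
  as.numeric(ad_value(node))
}
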