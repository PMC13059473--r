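#' Projection head parameters (into the contrastive space)
#' @param input_width input representation width
#' @param output_width contrastive-space width
#' @param seed init seed
#' @export
projection_head <- function(input_width, output_width = 32L, seed = 1L) {
  W <- with_seed(derive_seed(seed, "projW"),
                 matrix(stats::rnorm(input_width * output_width,
                                     sd = sqrt(2 / input_width)),
                        input_width, output_width))
  list(W = W, b = matrix(0, 1L, output_width),
       output_width = as.integer(output_width))
}

#' Project representations into the contrastive space
#'
#' `H = LayerNorm(ReLU(Z W + b))` row-wise: each sample is rectified,
#' affinely mapped and normalized to zero mean / unit variance across
#' features.
#' @param Z samples x input_width matrix
#' @param head [projection_head()]
#' @return samples x output_width matrix
#' @export
project <- function(Z, head) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(head$W)) {
    cmhs_stop("input width does not match projection head",
              "cmhs_dimension_error")
  }
  ad_tape_reset()
  node <- ad_layernorm_row(ad_relu(ad_add(ad_matmul(ad_const(Z),
                                                    ad_const(head$W)),
                                          ad_const(head$b))))
  ad_value(node)
}

#' Temperature-scaled cosine similarity matrix
#'
#' Rows of both inputs are unit-normalized before the inner product, so
#' `S_ij = cos(h_g_i, h_s_j) / tau` and `|S_ij| <= 1/tau`. Zero-norm rows
#' yield zero similarities with a warning.
#' @param H_g,H_s samples x width matrices (graph / sequence projections)
#' @param tau temperature (> 0); values below 1 can push diagonal terms
#'   above 1 and make the alignment term of the loss negative
#' @return samples x samples similarity matrix
#' @export
similarity_matrix <- function(H_g, H_s, tau = 1) {
  stopifnot(tau > 0)
  H_g <- as.matrix(H_g); H_s <- as.matrix(H_s)
  stopifnot(ncol(H_g) == ncol(H_s))
  if (tau < 1) warning("tau < 1 lets similarities exceed 1")
  unit <- function(H) {
    nrm <- sqrt(rowSums(H * H))
    if (any(nrm < 1e-12)) warning("zero-norm row; similarity set to 0")
    H / pmax(nrm, 1e-12)
  }
  (unit(H_g) %*% t(unit(H_s))) / tau
}

#' Contrastive alignment loss
#'
#' Positive pairs are the diagonal (the two modality views of the same
#' pMHC pair), negatives all off-diagonal pairs:
#' `[sum_i (1 - S_ii) + sum_{i != j} max(0, S_ij - margin)] / B^2`.
#' @param S square similarity matrix
#' @param margin hinge margin for negatives
#' @export
contrastive_loss <- function(S, margin = 0.5) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S))
  B <- nrow(S)
  pos <- sum(1 - diag(S))
  neg <- sum(pmax(0, (S - margin)[row(S) != col(S)]))
  (pos + neg) / (B * B)
}

#' Fusion linear layer parameters
#' @param input_width concatenated width of the two projections
#' @param output_width fused representation width
#' @param seed init seed
#' @export
fusion_linear <- function(input_width, output_width = 32L, seed = 1L) {
  W <- with_seed(derive_seed(seed, "fuseW"),
                 matrix(stats::rnorm(input_width * output_width,
                                     sd = sqrt(2 / input_width)),
                        input_width, output_width))
  list(W = W, b = matrix(0, 1L, output_width))
}

#' Adaptive fusion of the graph and sequence projections
#'
#' A single linear layer over the concatenation: `z = [z_g || z_s] W + b`.
#' @param z_g,z_s samples x width matrices
#' @param fusion [fusion_linear()]
#' @return samples x output_width matrix
#' @export
fuse <- function(z_g, z_s, fusion) {
  z_g <- as.matrix(z_g); z_s <- as.matrix(z_s)
  stopifnot(nrow(z_g) == nrow(z_s))
  zc <- cbind(z_g, z_s)
  if (ncol(zc) != nrow(fusion$W)) {
    cmhs_stop("fusion input width mismatch", "cmhs_dimension_error")
  }
  zc %*% fusion$W + matrix(fusion$b, nrow(zc), ncol(fusion$W), byrow = TRUE)
}

#' Affinity regression head parameters
#' @param input_width fused representation width
#' @param seed init seed
#' @export
affinity_head <- function(input_width, seed = 1L) {
  W <- with_seed(derive_seed(seed, "headW"),
                 matrix(stats::rnorm(input_width, sd = sqrt(1 / input_width)),
                        input_width, 1L))
  list(W = W, b = matrix(0, 1L, 1L))
}

#' Predict normalized affinity from a fused representation
#'
#' Sigmoid-capped linear head, matching the [0, 1] range of
#' [normalize_ic50()].
#' @param z samples x width matrix
#' @param head [affinity_head()]
#' @return numeric vector in (0, 1)
#' @export
predict_affinity <- function(z, head) {
  z <- as.matrix(z)
  as.numeric(stats::plogis(z %*% head$W + head$b[1L]))
}

#' Combined training loss
#'
#' `lambda * MSE(preds, targets) + beta_cont * contrastive_loss(S)`, with
#' the two components reported separately.
#' @param preds,targets numeric vectors of equal length
#' @param S similarity matrix for the contrastive term (ignored when
#'   `beta_cont = 0`)
#' @param cfg list with `lambda`, `beta_cont`, `margin`
#' @return list: `total`, `mse`, `contrastive`
#' @export
total_loss <- function(preds, targets, S = NULL,
                       cfg = list(lambda = 1, beta_cont = 0.1,
                                  margin = 0.5)) {
  stopifnot(length(preds) == length(targets))
  mse <- mean((preds - targets)^2)
  cont <- if (cfg$beta_cont > 0 && !is.null(S)) {
    contrastive_loss(S, cfg$margin)
  } else 0
  list(total = cfg$lambda * mse + cfg$beta_cont * cont,
       mse = mse, contrastive = cont)
}
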