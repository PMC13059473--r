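#' GAT layer parameters
#'
#' Per head: a projection `W` (input_width x head_width) and an attention
#' vector split into its source/target halves (the usual decomposition of
#' `a^T [W h_i || W h_j]` into `a_1^T W h_i + a_2^T W h_j`).
#' @param input_width node feature width (20 for raw BLOSUM features)
#' @param head_width per-head output width
#' @param heads number of attention heads K
#' @param slope leaky-ReLU negative slope for attention scores
#' @param combine "concat" (standard multi-head reading, output width
#'   `heads * head_width`) or "sum" (literal head-summation)
#' @param seed init seed
#' @export
gat_params <- function(input_width, head_width = 16L, heads = 2L,
                       slope = 0.2, combine = c("concat", "sum"),
                       seed = 1L) {
  combine <- match.arg(combine)
  mk <- function(tag, n, m) with_seed(derive_seed(seed, tag),
          matrix(stats::rnorm(n * m, sd = sqrt(2 / n)), n, m))
  heads_list <- lapply(seq_len(heads), function(k) list(
    W = mk(paste0("gatW", k), input_width, head_width),
    a1 = mk(paste0("gata1", k), head_width, 1L),
    a2 = mk(paste0("gata2", k), head_width, 1L)))
  list(heads = heads_list, slope = slope, combine = combine,
       head_width = as.integer(head_width), n_heads = as.integer(heads))
}

# Autodiff core. X: n x d node; returns list(H = node, alpha = list of
# per-head attention matrices (plain values, rows summing to 1 over
# neighbors incl. self-loop)).
.gat_forward <- function(X, A_mm, pn, slope, combine) {
  n <- nrow(ad_value(X))
  mask <- (A_mm + diag(n)) > 0          # self-loops for well-definedness
  ones_row <- ad_const(matrix(1, 1L, n))
  ones_col <- ad_const(matrix(1, n, 1L))
  outs <- list(); alphas <- list()
  for (k in seq_along(pn)) {
    h <- ad_matmul(X, pn[[k]]$W)
    f1 <- ad_matmul(h, pn[[k]]$a1)      # n x 1, source term
    f2 <- ad_matmul(h, pn[[k]]$a2)      # n x 1, target term
    scores <- ad_add(ad_matmul(f1, ones_row),
                     ad_matmul(ones_col, ad_t(f2)))
    alpha <- ad_softmax_row(ad_leaky_relu(scores, slope), mask * 1)
    alphas[[k]] <- ad_value(alpha)
    outs[[k]] <- ad_relu(ad_matmul(alpha, h))
  }
  H <- if (combine == "concat") {
    do.call(ad_cbind, outs)
  } else {
    out <- outs[[1L]]
    if (length(outs) > 1L) for (k in 2L:length(outs)) {
      out <- ad_add(out, outs[[k]])
    }
    out
  }
  list(H = H, alpha = alphas)
}

#' Graph attention layer over the MHC contact graph
#'
#' Multi-head attention with leaky-ReLU-scored, softmax-normalized
#' coefficients over each node's contact neighborhood (self-loops added).
#' Node inputs are the raw BLOSUM50 encodings by design.
#'
#' @param X_MB n x d node feature matrix
#' @param A_mm symmetric 0/1 contact adjacency
#' @param params [gat_params()]
#' @return list: `H` (n x output_width), `alpha` (per-head attention
#'   matrices whose rows sum to 1 over the closed neighborhood)
#' @export
gat_layer <- function(X_MB, A_mm, params) {
  stopifnot(nrow(X_MB) == nrow(A_mm))
  ad_tape_reset()
  pn <- lapply(params$heads, function(h) list(W = ad_const(h$W),
                                              a1 = ad_const(h$a1),
                                              a2 = ad_const(h$a2)))
  res <- .gat_forward(ad_const(as.matrix(X_MB)), as.matrix(A_mm), pn,
                      params$slope, params$combine)
  list(H = ad_value(res$H), alpha = res$alpha)
}

#' Cross-attention parameters (MHC against peptide nodes)
#' @param width_m MHC-side input width (GAT output width)
#' @param width_p peptide-side input width (20 for BLOSUM features)
#' @param proj_width shared projection width
#' @param slope leaky-ReLU slope
#' @param seed init seed
#' @export
cross_params <- function(width_m, width_p = 20L, proj_width = 16L,
                         slope = 0.2, seed = 1L) {
  mk <- function(tag, n, m) with_seed(derive_seed(seed, tag),
          matrix(stats::rnorm(n * m, sd = sqrt(2 / n)), n, m))
  list(W_m = mk("xW_m", width_m, proj_width),
       W_p = mk("xW_p", width_p, proj_width),
       a1 = mk("xa1", proj_width, 1L), a2 = mk("xa2", proj_width, 1L),
       slope = slope)
}

# Autodiff core: returns |V_M| x |V_P| score node, softmax-normalized over
# peptide nodes within the candidate mask; non-candidate rows stay zero.
.cross_forward <- function(Hm, Xpb, pn, slope, cand_mask) {
  nm <- nrow(ad_value(Hm)); np <- nrow(ad_value(Xpb))
  f1 <- ad_matmul(ad_matmul(Hm, pn$W_m), pn$a1)    # nm x 1
  f2 <- ad_matmul(ad_matmul(Xpb, pn$W_p), pn$a2)   # np x 1
  scores <- ad_add(ad_matmul(f1, ad_const(matrix(1, 1L, np))),
                   ad_matmul(ad_const(matrix(1, nm, 1L)), ad_t(f2)))
  ad_softmax_row(ad_leaky_relu(scores, slope), cand_mask)
}

#' Cross-attention edge scores between MHC and peptide nodes
#'
#' Scores `e_ij = LeakyReLU(a^T [W_m h_m_i || W_p x_p_j])` are computed on
#' the candidate edges of the heterogeneous graph and softmax-normalized
#' over peptide nodes for each MHC node, so every candidate row sums to 1.
#' MHC nodes with no candidate edges keep an all-zero row.
#'
#' @param H_m |V_M| x width_m MHC representations (GAT output)
#' @param X_PB |V_P| x width_p peptide node features
#' @param params [cross_params()]
#' @param candidates 0/1 candidate-edge matrix (|V_M| x |V_P|); default all
#' @return |V_M| x |V_P| score matrix
#' @export
cross_attention_scores <- function(H_m, X_PB, params, candidates = NULL) {
  H_m <- as.matrix(H_m); X_PB <- as.matrix(X_PB)
  if (is.null(candidates)) candidates <- matrix(1, nrow(H_m), nrow(X_PB))
  ad_tape_reset()
  pn <- list(W_m = ad_const(params$W_m), W_p = ad_const(params$W_p),
             a1 = ad_const(params$a1), a2 = ad_const(params$a2))
  ad_value(.cross_forward(ad_const(H_m), ad_const(X_PB), pn, params$slope,
                          as.matrix(candidates)))
}

#' Top-k edge-induced subgraph extraction
#'
#' For each peptide node, keep its k highest-scoring incident candidate
#' edges (all kept when fewer than k exist); ties break toward the lower
#' MHC node index. The induced subgraph keeps every peptide node plus the
#' MHC endpoints of selected edges.
#'
#' @param E |V_M| x |V_P| score matrix
#' @param k edges kept per peptide node
#' @param candidates 0/1 candidate mask; default `E != 0`
#' @return `cmhs_subgraph`: `selected` (list of MHC index vectors, ranked
#'   by descending score), `V_sub` (selected MHC nodes), `E_sub` (edge
#'   data.frame m, p), `k`
#' @export
topk_extract <- function(E, k, candidates = NULL) {
  E <- as.matrix(E)
  stopifnot(k >= 1L)
  if (is.null(candidates)) candidates <- (E != 0) * 1
  np <- ncol(E)
  selected <- vector("list", np)
  for (j in seq_len(np)) {
    cand <- which(candidates[, j] > 0)
    if (!length(cand)) { selected[[j]] <- integer(0); next }
    ord <- cand[order(-E[cand, j], cand)]
    selected[[j]] <- ord[seq_len(min(k, length(ord)))]
  }
  e_sub <- data.frame(
    m = unlist(selected),
    p = rep(seq_len(np), vapply(selected, length, 1L)))
  structure(list(selected = selected,
                 V_sub = sort(unique(e_sub$m)),
                 E_sub = e_sub, k = as.integer(k)),
            class = "cmhs_subgraph")
}

#' Cross adjacencies induced by a top-k selection
#'
#' Selected cells carry their cross-attention score; everything else is 0.
#' `A_mp` is MHC x peptide; `A_pm` is the peptide x MHC counterpart built
#' from the same selection (identical nonzero pattern, transposed).
#' @param sel `cmhs_subgraph` from [topk_extract()]
#' @param E the score matrix the selection was made on
#' @return list with `A_mp` and `A_pm`
#' @export
selection_to_adjacency <- function(sel, E) {
  E <- as.matrix(E)
  A_mp <- matrix(0, nrow(E), ncol(E))
  if (nrow(sel$E_sub)) {
    cells <- cbind(sel$E_sub$m, sel$E_sub$p)
    A_mp[cells] <- E[cells]
  }
  list(A_mp = A_mp, A_pm = t(A_mp))
}

#' Combine the two cross-edge adjacencies into one link matrix
#'
#' `A = k_weight * (A_mp + t(A_pm))` in MHC x peptide orientation (the
#' peptide-to-MHC matrix is transposed into the common orientation first).
#' @param A_mp MHC x peptide matrix
#' @param A_pm peptide x MHC matrix
#' @param k_weight combination weight (0.5 averages the two directions)
#' @export
combine_links <- function(A_mp, A_pm, k_weight = 0.5) {
  A_mp <- as.matrix(A_mp); A_pm <- as.matrix(A_pm)
  if (!identical(dim(A_mp), rev(dim(A_pm)))) {
    cmhs_stop("A_mp and A_pm dimensions do not conform",
              "cmhs_dimension_error")
  }
  k_weight * (A_mp + t(A_pm))
}

#' GCN direction parameters
#' @param input_width source node feature width
#' @param output_width output width
#' @param activation "relu", "tanh" or "identity"
#' @param seed init seed
#' @export
gcn_params <- function(input_width, output_width = 16L,
                       activation = c("relu", "tanh", "identity"),
                       seed = 1L) {
  activation <- match.arg(activation)
  Theta <- with_seed(derive_seed(seed, "gcnTheta"),
                     matrix(stats::rnorm(input_width * output_width,
                                         sd = sqrt(2 / input_width)),
                            input_width, output_width))
  list(Theta = Theta, activation = activation)
}

.ad_activate <- function(node, activation) {
  switch(activation,
         relu = ad_relu(node),
         tanh = ad_tanh(node),
         identity = node)
}

# Autodiff core: Z = act( D_r^{-1/2} A D_c^{-1/2} H_src Theta )
.gcn_forward <- function(H_src, A_dir, Theta, activation) {
  .ad_activate(ad_matmul(ad_matmul(ad_gcn_norm(A_dir), H_src), Theta),
               activation)
}

#' One GCN propagation along a typed cross-edge direction
#'
#' `Z = act(D_t^{-1/2} A D_s^{-1/2} H_src Theta)`; the output lives on the
#' target-side nodes (rows of `A_dir`). Degrees are computed on `|A|` with
#' an epsilon floor since noise injection can leave non-positive entries.
#'
#' @param H_src source node features (rows match columns of `A_dir`)
#' @param A_dir target x source adjacency
#' @param params [gcn_params()]
#' @return target x output_width matrix
#' @export
gcn_direction <- function(H_src, A_dir, params) {
  H_src <- as.matrix(H_src); A_dir <- as.matrix(A_dir)
  if (ncol(A_dir) != nrow(H_src)) {
    cmhs_stop("A_dir columns must match H_src rows", "cmhs_dimension_error")
  }
  ad_tape_reset()
  ad_value(.gcn_forward(ad_const(H_src), ad_const(A_dir),
                        ad_const(params$Theta), params$activation))
}

#' Fusion parameters for the two GCN directions
#'
#' The convex weight alpha is re-parameterized through a sigmoid of an
#' unconstrained scalar so it stays in (0, 1) under gradient updates;
#' beta = 1 - alpha.
#' @param alpha_init initial weight in (0, 1)
#' @export
fusion_params <- function(alpha_init = 0.5) {
  stopifnot(alpha_init > 0, alpha_init < 1)
  list(alpha_logit = stats::qlogis(alpha_init))
}

#' Fuse the two GCN directions into the graph-level representation
#'
#' The MHC-side and peptide-side outputs have different node counts, so
#' each is masked-mean-pooled to a graph-level vector first, then combined
#' convexly: `Z_final = alpha * pool(Z_mp) + (1 - alpha) * pool(Z_pm)`.
#'
#' @param Z_mp MHC-side GCN output (nodes x width)
#' @param Z_pm peptide-side GCN output (nodes x width)
#' @param fusion [fusion_params()]
#' @param mask_m,mask_p optional 0/1 pooling masks over nodes
#' @return graph-level numeric vector
#' @export
fuse_directions <- function(Z_mp, Z_pm, fusion, mask_m = NULL,
                            mask_p = NULL) {
  Z_mp <- as.matrix(Z_mp); Z_pm <- as.matrix(Z_pm)
  if (ncol(Z_mp) != ncol(Z_pm)) {
    cmhs_stop("fused directions must share output width",
              "cmhs_dimension_error")
  }
  alpha <- stats::plogis(fusion$alpha_logit)
  pool <- function(Z, mask) {
    rows <- if (is.null(mask)) seq_len(nrow(Z)) else which(mask > 0)
    colMeans(Z[rows, , drop = FALSE])
  }
  alpha * pool(Z_mp, mask_m) + (1 - alpha) * pool(Z_pm, mask_p)
}
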