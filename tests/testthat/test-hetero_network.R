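test_that("GAT attention rows are simplex weights over neighborhoods", {
  set.seed(10)
  n <- 7L
  A <- random_connected_adj(n)
  X <- matrix(rnorm(n * 20L), n, 20L)
  params <- gat_params(20L, head_width = 4L, heads = 3L, seed = 2)
  out <- gat_layer(X, A, params)
  expect_equal(dim(out$H), c(n, 12L))          # concat of 3 heads
  for (al in out$alpha) {
    expect_equal(rowSums(al), rep(1, n), tolerance = 1e-6)
    # support is exactly the closed neighborhood (contacts + self)
    expect_true(all((al > 0) == ((A + diag(n)) > 0)))
  }
  # identical node features give uniform attention over each neighborhood
  Xc <- matrix(1, n, 20L) %*% diag(20L)
  outc <- gat_layer(matrix(1, n, 20L), A, params)
  deg <- rowSums(A + diag(n))
  expect_equal(outc$alpha[[1L]], (A + diag(n)) / deg, tolerance = 1e-8)
})

test_that("GAT matches a hand-evaluated scalar case", {
  # 2 nodes, 1 head, width 1: all quantities are scalars
  x <- c(0.3, -0.8)
  w <- 1.7; a1 <- 0.4; a2 <- -1.1; slope <- 0.2
  params <- list(heads = list(list(W = matrix(w), a1 = matrix(a1),
                                   a2 = matrix(a2))),
                 slope = slope, combine = "concat", head_width = 1L,
                 n_heads = 1L)
  A <- matrix(c(0, 1, 1, 0), 2)
  out <- gat_layer(matrix(x, 2, 1), A, params)
  h <- w * x
  lrelu <- function(z) ifelse(z > 0, z, slope * z)
  s <- outer(a1 * h, a2 * h, `+`)              # s_ij = a1 h_i + a2 h_j
  al <- exp(lrelu(s)); al <- al / rowSums(al)
  expect_equal(out$alpha[[1L]], al, tolerance = 1e-10)
  expect_equal(out$H, matrix(pmax(al %*% h, 0), 2, 1), tolerance = 1e-10)
})

test_that("head summation variant collapses the concat width", {
  set.seed(11)
  A <- random_connected_adj(5)
  X <- matrix(rnorm(100), 5, 20)
  ps <- gat_params(20L, 6L, 2L, combine = "sum", seed = 3)
  expect_equal(dim(gat_layer(X, A, ps)$H), c(5L, 6L))
})

test_that("cross-attention normalizes candidate rows over peptide nodes", {
  set.seed(12)
  Hm <- matrix(rnorm(6 * 8), 6, 8)
  Xp <- matrix(rnorm(4 * 20), 4, 20)
  params <- cross_params(8L, 20L, proj_width = 5L, seed = 4)
  cand <- matrix(0, 6, 4); cand[c(2, 3, 5), ] <- 1
  E <- cross_attention_scores(Hm, Xp, params, cand)
  expect_equal(rowSums(E)[c(2, 3, 5)], rep(1, 3), tolerance = 1e-6)
  expect_equal(rowSums(E)[c(1, 4, 6)], rep(0, 3))   # no-candidate rows
  # identical peptide columns give uniform scores 1/|V_P|
  Xp1 <- Xp[rep(1L, 4L), ]
  E1 <- cross_attention_scores(Hm, Xp1, params, cand)
  expect_equal(E1[2, ], rep(0.25, 4), tolerance = 1e-8)
})

test_that("cross-attention matches a hand-evaluated 2x2 softmax", {
  params <- list(W_m = matrix(1), W_p = matrix(1), a1 = matrix(1),
                 a2 = matrix(1), slope = 0.2)
  Hm <- matrix(c(0.5, -0.2), 2, 1)
  Xp <- matrix(c(1.0, -1.5), 2, 1)
  E <- cross_attention_scores(Hm, Xp, params)
  lrelu <- function(z) ifelse(z > 0, z, 0.2 * z)
  s <- outer(c(0.5, -0.2), c(1.0, -1.5), `+`)
  ex <- exp(lrelu(s))
  expect_equal(E, ex / rowSums(ex), tolerance = 1e-10)
})

test_that("topk_extract equals the sort-and-slice oracle with ties", {
  set.seed(13)
  for (rep in 1:500) {
    nm <- sample(2:8, 1L); np <- sample(1:5, 1L); k <- sample(1:4, 1L)
    # coarse grid of scores forces frequent ties
    E <- matrix(sample(seq(0, 1, 0.25), nm * np, replace = TRUE), nm, np)
    cand <- matrix(rbinom(nm * np, 1, 0.8), nm, np)
    sel <- topk_extract(E, k, cand)
    expect_identical(sel$selected, oracle_topk(E, k, cand))
    expect_equal(vapply(sel$selected, length, 1L),
                 pmin(k, colSums(cand > 0)))
  }
})

test_that("topk selection satisfies the subgraph definition", {
  E <- matrix(c(0.4, 0.4, 0.4, 0.1, 0.9, 0.3), 3, 2)
  sel <- topk_extract(E, 2, matrix(1, 3, 2))
  expect_equal(sel$selected[[1L]], c(1L, 2L))  # ties -> lower index
  expect_equal(sel$selected[[2L]], c(2L, 3L))
  expect_equal(sel$V_sub, c(1L, 2L, 3L))
  expect_equal(nrow(sel$E_sub), 4L)
  # saturation: k beyond candidate count keeps everything
  sel2 <- topk_extract(E, 10, matrix(1, 3, 2))
  expect_equal(nrow(sel2$E_sub), 6L)
  # k = 1 is the per-peptide argmax
  sel3 <- topk_extract(E, 1, matrix(1, 3, 2))
  expect_equal(unlist(sel3$selected), c(1L, 2L))
})

test_that("peptide permutation equivariance of selection", {
  set.seed(14)
  E <- matrix(runif(24), 6, 4)
  perm <- c(3L, 1L, 4L, 2L)
  sel <- topk_extract(E, 2)
  selp <- topk_extract(E[, perm], 2)
  expect_identical(selp$selected, sel$selected[perm])
  adj <- selection_to_adjacency(sel, E)
  adjp <- selection_to_adjacency(selp, E[, perm])
  expect_equal(adjp$A_mp, adj$A_mp[, perm])
})

test_that("selection_to_adjacency carries scores on selected cells", {
  E <- matrix(runif(15), 5, 3)
  sel <- topk_extract(E, 2)
  adj <- selection_to_adjacency(sel, E)
  expect_equal(sum(adj$A_mp != 0), 6L)
  for (j in 1:3) {
    expect_equal(adj$A_mp[sel$selected[[j]], j], E[sel$selected[[j]], j])
  }
  expect_equal(adj$A_pm, t(adj$A_mp))
  empty <- topk_extract(E, 1, candidates = matrix(0, 5, 3))
  z <- selection_to_adjacency(empty, E)
  expect_equal(z$A_mp, matrix(0, 5, 3))
})

test_that("combine_links averages the two orientations", {
  A_mp <- matrix(runif(6), 2, 3)
  expect_equal(combine_links(A_mp, t(A_mp)), A_mp)
  expect_equal(combine_links(A_mp * 0, t(A_mp) * 0), A_mp * 0)
  B_pm <- matrix(runif(6), 3, 2)
  expect_equal(combine_links(A_mp, B_pm, k_weight = 1), A_mp + t(B_pm))
  expect_error(combine_links(A_mp, matrix(0, 2, 3)),
               class = "cmhs_dimension_error")
})

test_that("gcn_direction implements normalized propagation", {
  # single unit edge, identity weights: target receives the source feature
  A <- matrix(c(1, 0), 1, 2)                   # 1 target, 2 sources
  H <- matrix(c(3, 7), 2, 1)
  p <- list(Theta = matrix(1), activation = "identity")
  expect_equal(gcn_direction(H, A, p), matrix(3))
  # linear in H for identity activation
  A2 <- matrix(runif(6), 2, 3)
  H2 <- matrix(rnorm(6), 3, 2)
  p2 <- list(Theta = matrix(rnorm(4), 2, 2), activation = "identity")
  expect_equal(gcn_direction(2 * H2, A2, p2), 2 * gcn_direction(H2, A2, p2))
  # hand-computed 2x2 weighted bipartite case
  A3 <- matrix(c(2, 0, 1, 3), 2, 2)
  H3 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  Th <- matrix(c(1, 0, 0, 1), 2, 2)
  dr <- 1 / sqrt(rowSums(A3)); dc <- 1 / sqrt(colSums(A3))
  want <- (A3 * outer(dr, dc)) %*% H3
  expect_equal(gcn_direction(H3, A3, list(Theta = Th,
                                          activation = "identity")), want)
  # negative entries (post-noise) are tolerated via |A| degrees
  A4 <- matrix(c(-0.5, 1, 0.2, -0.1), 2, 2)
  expect_true(all(is.finite(gcn_direction(H3, A4, p2))))
  expect_error(gcn_direction(H3, matrix(0, 2, 4), p2),
               class = "cmhs_dimension_error")
})

test_that("fuse_directions is a convex pooled combination", {
  Zm <- matrix(rnorm(12), 3, 4)
  Zp <- matrix(rnorm(8), 2, 4)
  f1 <- fusion_params(alpha_init = 1 - 1e-12)
  expect_equal(fuse_directions(Zm, Zp, f1), colMeans(Zm), tolerance = 1e-6)
  same <- fuse_directions(Zm, Zm, fusion_params(0.5))
  expect_equal(same, colMeans(Zm))
  out <- fuse_directions(Zm, Zp, fusion_params(0.3))
  lo <- pmin(colMeans(Zm), colMeans(Zp)); hi <- pmax(colMeans(Zm),
                                                     colMeans(Zp))
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  # masked pooling
  expect_equal(fuse_directions(Zm, Zp, f1, mask_m = c(1, 0, 0)),
               Zm[1L, ], tolerance = 1e-6)
  expect_error(fuse_directions(Zm, Zp[, 1:2], fusion_params()),
               class = "cmhs_dimension_error")
})

test_that("layers are deterministic given parameters", {
  set.seed(15)
  A <- random_connected_adj(6)
  X <- matrix(rnorm(120), 6, 20)
  ps <- gat_params(20L, 4L, 2L, seed = 9)
  expect_identical(gat_layer(X, A, ps)$H, gat_layer(X, A, ps)$H)
  p2 <- list(Theta = matrix(rnorm(40), 20, 2), activation = "relu")
  Ad <- matrix(runif(30), 5, 6)
  expect_identical(gcn_direction(X, Ad, p2), gcn_direction(X, Ad, p2))
})

test_that("structural branch is invariant under MHC relabeling", {
  set.seed(16)
  n <- 10L
  coords <- matrix(rnorm(3 * n, sd = 4), n, 3)
  pseudo <- c(2L, 5L, 8L)
  Xmb <- matrix(rnorm(20 * n), n, 20)
  Xpb <- matrix(rnorm(20 * 9), 9, 20)
  gp <- gat_params(20L, 4L, 2L, seed = 1)
  branch <- function(coords, Xmb, pseudo) {
    g <- build_hetero_graph(coords, pseudo, 9)
    H <- gat_layer(Xmb, g$A_mm, gp)$H
    cp <- cross_params(ncol(H), 20L, 5L, seed = 2)
    E <- cross_attention_scores(H, Xpb, cp, g$E_mp)
    sel <- topk_extract(E, 3, g$E_mp)
    adj <- selection_to_adjacency(sel, E)
    A <- combine_links(adj$A_mp, adj$A_pm)
    Zmp <- gcn_direction(Xpb, A, list(Theta = diag(20), activation = "relu"))
    Zpm <- gcn_direction(H, t(A), list(Theta = diag(8)[, 1:6],
                                       activation = "relu"))
    vs <- integer(n); vs[sel$V_sub] <- 1L
    fuse_directions(Zmp[, 1:6], Zpm, fusion_params(0.4), mask_m = vs)
  }
  base <- branch(coords, Xmb, pseudo)
  perm <- sample(n)
  inv <- order(perm)
  permuted <- branch(coords[perm, ], Xmb[perm, ], match(pseudo, perm))
  expect_equal(permuted, base, tolerance = 1e-8)
})
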