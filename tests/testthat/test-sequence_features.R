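test_that("blosum50_encode reproduces the pinned matrix rows", {
  m <- blosum50_encode("A", 1L)
  expect_equal(unname(m[1L, "A"]), 5)          # canonical BLOSUM50 A-A
  expect_equal(unname(blosum50_matrix()["W", "W"]), 15)
  expect_equal(unname(blosum50_matrix()["R", "K"]), 3)
  enc <- blosum50_encode("ACDE", 7L)
  expect_equal(dim(enc), c(7L, 20L))
  expect_true(all(enc[5:7, ] == 0))            # pad rows
  # substitution-matrix symmetry through the encoding
  expect_equal(unname(blosum50_encode("AC")[1L, "C"]),
               unname(blosum50_encode("CA")[1L, "A"]))
  expect_error(blosum50_encode("ABD"), "position 2",
               class = "cmhs_encoding_error")
  expect_error(blosum50_encode("ACD", 2L), class = "cmhs_dimension_error")
})

test_that("lora_update is a pure low-rank additive update", {
  W <- diag(2)
  ad <- lora_adapter(A = matrix(c(0, 1), 2, 1), B = matrix(c(1, 0), 2, 1))
  expect_equal(lora_update(W, ad), matrix(c(1, 0, 1, 1), 2, 2))
  expect_equal(W, diag(2))                     # W not mutated
  # zero A => identity update
  z <- lora_adapter(A = matrix(0, 4, 2), B = matrix(rnorm(6), 3, 2))
  W2 <- matrix(rnorm(12), 3, 4)
  expect_equal(lora_update(W2, z), W2)
  # full rank recovers any target update
  delta <- matrix(rnorm(12), 3, 4)
  full <- lora_adapter(A = diag(4), B = delta)
  expect_equal(lora_update(W2, full), W2 + delta)
  expect_error(lora_update(W2, lora_adapter(A = matrix(0, 5, 1),
                                            B = matrix(0, 3, 1))),
               class = "cmhs_dimension_error")
})

test_that("low-rank structure holds for random adapters", {
  set.seed(3)
  for (rep in 1:50) {
    da <- sample(3:8, 1L); db <- sample(3:8, 1L)
    r <- sample.int(min(da, db) - 1L, 1L)
    ad <- lora_adapter(A = matrix(rnorm(db * r), db, r),
                       B = matrix(rnorm(da * r), da, r))
    d <- svd(lora_update(matrix(0, da, db), ad))$d
    expect_lte(sum(d > 1e-9 * max(d)), r)
  }
})

test_that("adapted_attention applies per-projection updates", {
  M <- matrix(c(1, 2), 1, 2)
  base <- list(Q = diag(2), K = diag(2), V = matrix(1, 2, 2))
  zero <- lapply(c(Q = "Q", K = "K", V = "V"), function(t)
    lora_adapter(A = matrix(0, 2, 1), B = matrix(0, 2, 1), t))
  out <- adapted_attention(M, base, zero)
  expect_equal(out$Q, M %*% base$Q)
  expect_equal(out$V, M %*% base$V)
  # hand-computed 1-token width-2 case
  adQ <- zero
  adQ$Q <- lora_adapter(A = matrix(c(1, 0), 2, 1),
                        B = matrix(c(0, 1), 2, 1), "Q")
  out2 <- adapted_attention(M, base, adQ)
  expect_equal(out2$Q, M %*% (diag(2) + matrix(c(0, 1, 0, 0), 2, 2)))
  # doubling B doubles the update
  adQ2 <- adQ
  adQ2$Q <- lora_adapter(A = adQ$Q$A, B = 2 * adQ$Q$B, "Q")
  expect_equal(adapted_attention(M, base, adQ2)$Q - out$Q,
               2 * (out2$Q - out$Q))
  expect_error(adapted_attention(M, base, adQ["Q"]),
               "missing adapter", class = "cmhs_config_error")
})

test_that("embedders are deterministic, sensitive and guard adapters", {
  st <- embedder_stub(width = 16L)
  e1 <- embed_sequence("ACDEFGHI", st)
  expect_identical(e1, embed_sequence("ACDEFGHI", st))
  expect_false(isTRUE(all.equal(e1, embed_sequence("ACDEFGHL", st))))
  expect_equal(dim(embed_sequence("ACDE", st, target_length = 9L)),
               c(9L, 16L))
  expect_error(embed_sequence("ACDE", st, adapters = list()),
               class = "cmhs_config_error")

  tiny <- embedder_tiny_attention(width = 8L)
  zero <- lapply(c(Q = "Q", K = "K", V = "V"), function(t)
    lora_adapter(A = matrix(0, 8, 2), B = matrix(0, 8, 2), t))
  expect_equal(embed_sequence("ACDEFGHI", tiny, zero),
               embed_sequence("ACDEFGHI", tiny))
  nz <- zero
  nz$V <- lora_adapter(A = matrix(0.3, 8, 2), B = matrix(0.2, 8, 2), "V")
  expect_false(isTRUE(all.equal(embed_sequence("ACDEFGHI", tiny, nz),
                                embed_sequence("ACDEFGHI", tiny))))
})

test_that("frozen base stays fixed while adapters train", {
  # one AdamW step on a toy loss through the LoRA-adapted projection:
  # gradient must reach A and B but never the frozen base weight
  set.seed(4)
  M <- matrix(rnorm(6), 2, 3)
  ad_tape_reset()
  Wbase <- ad_const(matrix(rnorm(9), 3, 3))
  A <- ad_param(matrix(0, 3, 2))
  B <- ad_param(matrix(rnorm(6), 3, 2))
  W0 <- Wbase$val
  Q <- ad_matmul(ad_const(M), ad_add(Wbase, ad_matmul(B, ad_t(A))))
  loss <- ad_sum(ad_mul(Q, Q))
  ad_backward(loss)
  expect_null(Wbase$grad)
  expect_true(max(abs(A$grad)) > 0)
  A0 <- A$val
  adamw_step(list(A, B), lr = 1e-2)
  expect_false(isTRUE(all.equal(A$val, A0)))
  expect_identical(Wbase$val, W0)
})

test_that("concat_features fixes the embedder|BLOSUM column layout", {
  bl <- blosum50_encode("ACDEFGHI", 12L)
  em <- embed_sequence("ACDEFGHI", embedder_stub(320L), target_length = 12L)
  enc <- concat_features(bl, em, "peptide")
  expect_equal(ncol(enc$features), 340L)
  expect_equal(enc$mask, c(rep(1L, 8L), rep(0L, 4L)))
  expect_equal(enc$features[, 321:340], bl, ignore_attr = TRUE)
  expect_equal(enc$features[, 1:320], em, ignore_attr = TRUE)
  zero <- concat_features(bl, em * 0, "peptide", mask = enc$mask)
  expect_equal(zero$features[, 321:340], bl)
  expect_error(concat_features(bl, em[1:3, ]),
               class = "cmhs_dimension_error")
})

test_that("embedding noise is seeded, maskable and off at inference", {
  X <- matrix(rnorm(60), 10, 6)
  sp <- noise_spec(6L, mu = 0.3, log_sigma = log(0.2))
  expect_identical(apply_embedding_noise(X, sp, 1, training = FALSE), X)
  off <- noise_spec(6L, enabled = FALSE)
  expect_identical(apply_embedding_noise(X, off, 1, training = TRUE), X)
  tiny <- noise_spec(6L, mu = 0, log_sigma = -40)
  expect_equal(apply_embedding_noise(X, tiny, 1), X, tolerance = 1e-12)
  expect_identical(apply_embedding_noise(X, sp, 9),
                   apply_embedding_noise(X, sp, 9))
  expect_false(identical(apply_embedding_noise(X, sp, 9),
                         apply_embedding_noise(X, sp, 10)))
})

test_that("injected noise moments match (mu, sigma) at 1e5 draws", {
  n <- 1e5L
  X <- matrix(0, n, 1L)
  sp <- noise_spec(1L, mu = 1, log_sigma = log(0.5))
  draws <- apply_embedding_noise(X, sp, seed = 123)[, 1L]
  se_mean <- 0.5 / sqrt(n)
  expect_lt(abs(mean(draws) - 1), 3 * se_mean)
  se_sd <- 0.5 / sqrt(2 * n)
  expect_lt(abs(sd(draws) - 0.5), 3 * se_sd)
})

test_that("feature pyramid honors its shape and pooling contracts", {
  e <- 12L; W <- e + 20L
  st <- embedder_stub(e)
  mk <- function(seq, role, tl = nchar(seq)) {
    concat_features(blosum50_encode(seq, tl),
                    embed_sequence(seq, st, target_length = tl), role)
  }
  Xm <- mk(strrep("ACDEFGHIKLMNPQRSTVWY", 2), "MHC")
  Xp <- mk("ACDEFGHIK", "peptide", 12L)
  pp <- pyramid_params(W, seed = 5)            # channels default to W
  s <- feature_pyramid(Xm, Xp, pp)
  expect_length(s, 6L * W)                     # 3 levels x 2W each
  pp2 <- pyramid_params(W, channels = 7L, seed = 5)
  expect_length(feature_pyramid(Xm, Xp, pp2), 2L * W + 4L * 7L)
  # all-zero inputs with zero biases give the zero vector
  z <- encoded_sequence(matrix(0, 10, W), rep(1, 10), "MHC")
  zp <- encoded_sequence(matrix(0, 12, W), c(rep(1, 9), 0, 0, 0), "peptide")
  expect_equal(feature_pyramid(z, zp, pp), rep(0, 6L * W))
  # position sensitivity: shuffling the peptide changes S_final
  Xp_shuf <- mk("KIHGFEDCA", "peptide", 12L)
  expect_false(isTRUE(all.equal(feature_pyramid(Xm, Xp, pp),
                                feature_pyramid(Xm, Xp_shuf, pp))))
})

test_that("identity kernels reduce layer 1 to the layer 0 maximum", {
  # single channel, width-1 kernels with unit weight: CNN output equals
  # its input, so the level-1 pool equals the level-0 max per track
  X <- matrix(c(0.2, 1.5, 0.7), 3, 1)
  P <- matrix(c(0.4, 0.1), 2, 1)
  pp <- list(W1m = matrix(1, 1, 1), b1m = matrix(0, 1, 1),
             W2m = matrix(1, 1, 1), b2m = matrix(0, 1, 1),
             W1p = matrix(1, 1, 1), b1p = matrix(0, 1, 1),
             kernel_m = 1L, kernel_p = 1L, channels = 1L)
  s <- feature_pyramid(encoded_sequence(X, rep(1, 3), "MHC"),
                       encoded_sequence(P, rep(1, 2), "peptide"), pp)
  expect_equal(s, c(1.5, 0.4, 1.5, 0.4, 1.5, 0.4))
})
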