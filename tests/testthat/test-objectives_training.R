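test_that("project applies ReLU, affine map and LayerNorm per sample", {
  set.seed(17)
  Z <- matrix(rnorm(40), 8, 5)
  head <- projection_head(5L, 6L, seed = 3)
  H <- project(Z, head)
  expect_equal(rowMeans(H), rep(0, 8), tolerance = 1e-5)
  expect_equal(apply(H, 1, function(r) mean(r^2)), rep(1, 8),
               tolerance = 1e-3)
  Z2 <- Z[c(1, 1, 3:8), ]
  expect_equal(project(Z2, head)[1L, ], project(Z2, head)[2L, ])
  # hand case: 1x2 input, unit affine
  hw <- list(W = diag(2), b = matrix(0, 1, 2), output_width = 2L)
  x <- matrix(c(3, -1), 1, 2)              # relu -> (3, 0)
  got <- project(x, hw)
  xc <- c(3, 0) - 1.5
  expect_equal(got, matrix(xc / sqrt(mean(xc^2) + 1e-5), 1),
               tolerance = 1e-8)
  expect_error(project(matrix(0, 2, 3), head),
               class = "cmhs_dimension_error")
})

test_that("similarity_matrix is temperature-scaled cosine", {
  H <- diag(3)
  expect_equal(diag(similarity_matrix(H, H)), rep(1, 3))
  expect_equal(similarity_matrix(H, H)[1, 2], 0)
  Hg <- matrix(rnorm(12), 3, 4); Hs <- matrix(rnorm(12), 3, 4)
  expect_warning(S2 <- similarity_matrix(Hg, Hs, tau = 0.5), "tau")
  expect_equal(S2, 2 * similarity_matrix(Hg, Hs, tau = 1))
  expect_true(all(abs(similarity_matrix(Hg, Hs)) <= 1 + 1e-12))
  Hz <- rbind(c(0, 0, 0, 0), rnorm(4))
  expect_warning(Sz <- similarity_matrix(Hz, Hs[1:2, ]), "zero-norm")
  expect_equal(Sz[1L, ], c(0, 0))
})

test_that("contrastive_loss matches its closed forms", {
  expect_equal(contrastive_loss(diag(3), margin = 0.5), 0)
  expect_equal(contrastive_loss(matrix(1, 2, 2), margin = 0.5), 0.25)
  # hinge inactive: loss is sum(1 - S_ii) / B^2
  set.seed(18)
  S <- matrix(runif(16, -1, 0.2), 4)
  diag(S) <- runif(4, 0.5, 1)
  expect_equal(contrastive_loss(S, margin = 0.3),
               sum(1 - diag(S)) / 16)
  # the identity is the minimizer over [-1, 1] entries at tau = 1
  for (rep in 1:200) {
    R <- matrix(runif(16, -1, 1), 4)
    expect_gte(contrastive_loss(R, 0.5), 0)
  }
})

test_that("fuse and predict_affinity implement the regression head", {
  fl <- fusion_linear(4L, 3L, seed = 5)
  zg <- matrix(rnorm(4), 2, 2); zs <- matrix(rnorm(4), 2, 2)
  expect_equal(fuse(zg, zs, fl), cbind(zg, zs) %*% fl$W)
  z0 <- list(W = matrix(0, 4, 3), b = matrix(c(1, 2, 3), 1, 3))
  expect_equal(fuse(zg, zs, z0), matrix(c(1, 2, 3), 2, 3, byrow = TRUE))
  # linearity in each argument
  expect_equal(fuse(2 * zg, zs, fl) + fuse(zg * 0, zs, fl),
               fuse(zg, zs, fl) + fuse(zg, zs, fl))
  # hand case 2+2 -> 1
  fw <- list(W = matrix(c(1, -1, 0.5, 2), 4, 1), b = matrix(0.1, 1, 1))
  expect_equal(fuse(matrix(c(1, 2), 1), matrix(c(3, 4), 1), fw),
               matrix(1 - 2 + 1.5 + 8 + 0.1, 1, 1))
  hd <- affinity_head(3L, seed = 6)
  p <- predict_affinity(matrix(rnorm(9), 3, 3), hd)
  expect_true(all(p > 0 & p < 1))
  h0 <- list(W = matrix(0, 3, 1), b = matrix(0.7, 1, 1))
  expect_equal(predict_affinity(matrix(rnorm(3), 1, 3), h0), plogis(0.7))
  # monotone in each coordinate for positive weights
  hp <- list(W = matrix(c(1, 1, 1), 3, 1), b = matrix(0, 1, 1))
  expect_gt(predict_affinity(matrix(c(1, 1, 2), 1), hp),
            predict_affinity(matrix(c(1, 1, 1), 1), hp))
})

test_that("total_loss combines MSE and contrastive terms", {
  perfect <- total_loss(c(0.2, 0.8), c(0.2, 0.8), diag(2),
                        list(lambda = 1, beta_cont = 1, margin = 0.5))
  expect_equal(perfect$total, 0)
  pure <- total_loss(c(1, -1), c(0, 0), NULL,
                     list(lambda = 1, beta_cont = 0, margin = 0.5))
  expect_equal(pure$total, 1)
  expect_equal(pure$mse, 1)
  # known components 0.25 and 0.1 with lambda 1, beta 2
  S <- diag(c(0.8, 0.8))
  S[1, 2] <- S[2, 1] <- 0.2
  got <- total_loss(c(0.5, 0.5), c(0, 1), S,
                    list(lambda = 1, beta_cont = 2, margin = 0.5))
  expect_equal(got$contrastive, 0.1)
  expect_equal(got$mse, 0.25)
  expect_equal(got$total, 0.45)
})

test_that("training is seeded, learns, and reacts to the loss weights", {
  ds <- tiny_dataset(seed = 21)
  m1 <- train(ds, tiny_train_config(epochs = 2, seed = 7))
  m2 <- train(ds, tiny_train_config(epochs = 2, seed = 7))
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, ds, rows = 1:5), predict(m2, ds, rows = 1:5))
  # learnability smoke: loss drops over a short run
  m3 <- train(ds, tiny_train_config(epochs = 12, seed = 8))
  expect_lt(tail(m3$history$train_loss, 1), m3$history$train_loss[1])
  # beta changes the trajectory
  m4 <- train(ds, tiny_train_config(epochs = 2, seed = 7,
                                    loss = list(beta_cont = 0)))
  expect_false(identical(m4$history$train_loss, m1$history$train_loss))
  expect_equal(m4$history$contrastive, c(0, 0))
})

test_that("gradients reach both branches through the combined loss", {
  ds <- tiny_dataset(seed = 22)
  model <- cmhs_model(tiny_train_config(seed = 9))
  cache <- build_cache(model, ds)
  params <- model_parameters(model)
  ad_tape_reset()
  res <- with_seed(1, cmhs:::.forward_batch(model$pl, cache, ds$table,
                                            1:8, model$config, TRUE))
  ad_zero_grads(params)
  ad_backward(res$total)
  grads_on <- function(nm) !is.null(model$pl[[nm]]$grad) &&
    max(abs(model$pl[[nm]]$grad)) > 0
  # sequence branch: CNN + its projection head; graph branch: GAT,
  # cross-attention, GCN + its projection head; shared: fusion + head
  for (nm in c("W1m", "W1p", "Ws", "Wg", "Theta_m", "Theta_p", "Wf",
               "Wh", "noise_mu", "noise_log_sigma", "alpha_logit")) {
    expect_true(grads_on(nm), label = paste("grad on", nm))
  }
  expect_true(!is.null(model$pl$gat[[1L]]$W$grad))
  expect_true(!is.null(model$pl$cross$W_m$grad))
})

test_that("cross_validate builds disjoint seeded folds", {
  ds <- tiny_dataset(n_alleles = 2, n_peptides = 5, seed = 23)
  ds$table <- ds$table[1:10, ]
  cfg <- tiny_train_config(epochs = 1, seed = 11)
  cfg$train$folds <- 5L
  # 2-sample folds can hold a single class; the AUROC warning is expected
  cv <- suppressWarnings(cross_validate(ds, cfg))
  expect_length(cv$folds, 5L)
  expect_equal(as.integer(table(cv$fold_assignment)), rep(2L, 5L))
  cv2 <- suppressWarnings(cross_validate(ds, cfg))
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_true(all(is.finite(cv$mean[c("srcc", "pcc")])))
  cfg$train$folds <- 11L
  expect_error(cross_validate(ds, cfg), class = "cmhs_config_error")
})

test_that("checkpoints round-trip and reject mismatched shapes", {
  ds <- tiny_dataset(seed = 24)
  m <- train(ds, tiny_train_config(epochs = 1, seed = 12))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(predict(m2, ds, rows = 1:6), predict(m, ds, rows = 1:6),
               tolerance = 1e-10)
  # corrupt the stored width: loading must fail with a clear shape error
  obj <- jsonlite::fromJSON(readLines(f), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  obj$config$embedder$width <- 64L
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA)), f)
  expect_error(load_checkpoint(f), "expects",
               class = "cmhs_dimension_error")
})
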