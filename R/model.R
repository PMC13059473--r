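#' Default model/training configuration
#'
#' Defaults follow the conventions of the method: embedder width 320
#' (protein-language-model scale), BLOSUM width 20, two MHC CNN layers
#' (kernel 5) and one peptide layer (kernel 3), GAT on raw BLOSUM node
#' features, top-k = 5 cross edges per peptide node, AdamW (lr 1e-3,
#' weight decay 1e-2), 200 epochs, 5-fold cross-validation, loss weights
#' lambda = 1 and beta_cont = 0.1, contrastive temperature 1 and margin
#' 0.5. Every value can be overridden via [merge_config()]-style lists.
#' @return nested configuration list
#' @export
cmhs_config <- function() {
  list(
    seed = 1L,
    variant = "full",                   # or "sequence_only"
    embedder = list(kind = "stub", width = 320L, seed = 42L),
    lora = list(rank = 4L),
    noise = list(enabled = TRUE, init_sigma = 0.05),
    cnn = list(channels = NULL, kernel_m = 5L, kernel_p = 3L),
    gat = list(heads = 2L, width = 16L, slope = 0.2, combine = "concat"),
    cross = list(proj_width = 16L, slope = 0.2),
    topk = list(k = 5L),
    adj_noise = list(enabled = TRUE, sigma_min = 0.01, sigma_max = 0.5,
                     k = 1.0),
    gcn = list(width = 16L, activation = "relu"),
    fusion = list(alpha_init = 0.5),
    contrastive = list(proj_width = 32L, tau = 1.0, margin = 0.5),
    head = list(fusion_width = 32L),
    loss = list(lambda = 1.0, beta_cont = 0.1),
    structure = list(contact_threshold = 8),
    train = list(epochs = 200L, batch_size = 32L, lr = 1e-3,
                 weight_decay = 1e-2, folds = 5L, val_fraction = 0.2,
                 group_by_allele = TRUE)
  )
}

#' Desk-scale configuration (stub embedder width 32, 50 epochs)
#'
#' The small configuration used for end-to-end tests on synthetic data:
#' identical architecture, narrower widths. The optimizer steps are
#' larger than the full-scale defaults (lr 3e-3, weight decay 1e-3)
#' because a 50-epoch desk-scale run underfits at lr 1e-3; see the
#' methods vignette.
#' @param overrides optional nested list of overrides
#' @export
cmhs_small_config <- function(overrides = NULL) {
  cfg <- cmhs_config()
  cfg$embedder$width <- 32L
  cfg$cnn$channels <- 32L
  cfg$train$epochs <- 50L
  cfg$train$lr <- 3e-3
  cfg$train$weight_decay <- 1e-3
  merge_config(cfg, overrides)
}

#' pMHC dataset container
#'
#' @param table affinity data.frame (see [read_affinity_table()])
#' @param mhc_seqs named character vector of MHC sequences (names = mhc_id)
#' @param coords named list of n x 3 Calpha coordinate matrices per allele
#' @param pseudo_positions integer vector of 1-based binding-site indices
#'   (shared across alleles) or a named list per allele
#' @export
cmhs_dataset <- function(table, mhc_seqs, coords, pseudo_positions) {
  need <- unique(table$mhc_id)
  miss <- setdiff(need, names(mhc_seqs))
  if (length(miss)) cmhs_stop(paste0("missing MHC sequence(s): ",
                                     paste(miss, collapse = ", ")),
                              "cmhs_validation_error")
  miss <- setdiff(need, names(coords))
  if (length(miss)) cmhs_stop(paste0("missing structure(s): ",
                                     paste(miss, collapse = ", ")),
                              "cmhs_validation_error")
  structure(list(table = table, mhc_seqs = mhc_seqs, coords = coords,
                 pseudo_positions = pseudo_positions),
            class = "cmhs_dataset")
}

#' @export
print.cmhs_dataset <- function(x, ...) {
  cat(sprintf("<cmhs_dataset: %d pairs, %d alleles, %d peptides>\n",
              nrow(x$table), length(unique(x$table$mhc_id)),
              length(unique(x$table$peptide))))
  invisible(x)
}

.pseudo_for <- function(dataset, mhc_id) {
  pp <- dataset$pseudo_positions
  if (is.list(pp)) pp[[mhc_id]] else pp
}

#' Initialize an untrained model
#'
#' All trainable parameters (CNN pyramid, embedding-noise (mu, log sigma),
#' GAT heads, cross-attention, adjacency-noise gain, dual GCN, fusion
#' weight, projection heads, fusion linear and affinity head) are created
#' as autodiff parameter nodes, seeded from `config$seed`.
#' @param config configuration list (see [cmhs_config()])
#' @return object of class `cmhs_model`
#' @export
cmhs_model <- function(config = cmhs_config()) {
  cfg <- merge_config(cmhs_config(), config)
  e <- cfg$embedder$width
  feat_w <- e + 20L
  channels <- as.integer(cfg$cnn$channels %||% feat_w)
  cfg$cnn$channels <- channels
  seed <- cfg$seed
  embedder <- switch(cfg$embedder$kind,
    stub = embedder_stub(e, cfg$embedder$seed),
    tiny_attention = embedder_tiny_attention(e, cfg$embedder$seed),
    cmhs_stop(sprintf("unknown embedder kind '%s'", cfg$embedder$kind),
              "cmhs_config_error"))

  pyr <- pyramid_params(feat_w, channels, cfg$cnn$kernel_m,
                        cfg$cnn$kernel_p, derive_seed(seed, "pyr"))
  gatp <- gat_params(20L, cfg$gat$width, cfg$gat$heads, cfg$gat$slope,
                     cfg$gat$combine, derive_seed(seed, "gat"))
  gat_out <- if (cfg$gat$combine == "concat") {
    cfg$gat$heads * cfg$gat$width
  } else cfg$gat$width
  crossp <- cross_params(gat_out, 20L, cfg$cross$proj_width,
                         cfg$cross$slope, derive_seed(seed, "cross"))
  s_width <- 2L * feat_w + 4L * channels
  cw <- cfg$contrastive$proj_width
  fw <- cfg$head$fusion_width
  gw <- cfg$gcn$width
  ph_g <- projection_head(gw, cw, derive_seed(seed, "projg"))
  ph_s <- projection_head(s_width, cw, derive_seed(seed, "projs"))
  fl <- fusion_linear(2L * cw, fw, derive_seed(seed, "fuse"))
  ah <- affinity_head(fw, derive_seed(seed, "head"))
  th_m <- gcn_params(20L, gw, cfg$gcn$activation,
                     derive_seed(seed, "gcnm"))$Theta
  th_p <- gcn_params(gat_out, gw, cfg$gcn$activation,
                     derive_seed(seed, "gcnp"))$Theta

  pl <- list(
    W1m = ad_param(pyr$W1m, "W1m"), b1m = ad_param(pyr$b1m, "b1m"),
    W2m = ad_param(pyr$W2m, "W2m"), b2m = ad_param(pyr$b2m, "b2m"),
    W1p = ad_param(pyr$W1p, "W1p"), b1p = ad_param(pyr$b1p, "b1p"),
    noise_mu = ad_param(matrix(0, 1L, feat_w), "noise_mu"),
    noise_log_sigma = ad_param(matrix(log(cfg$noise$init_sigma), 1L,
                                      feat_w), "noise_log_sigma"),
    gat = lapply(seq_along(gatp$heads), function(k) list(
      W = ad_param(gatp$heads[[k]]$W, paste0("gatW", k)),
      a1 = ad_param(gatp$heads[[k]]$a1, paste0("gata1", k)),
      a2 = ad_param(gatp$heads[[k]]$a2, paste0("gata2", k)))),
    cross = list(W_m = ad_param(crossp$W_m, "xWm"),
                 W_p = ad_param(crossp$W_p, "xWp"),
                 a1 = ad_param(crossp$a1, "xa1"),
                 a2 = ad_param(crossp$a2, "xa2")),
    adj_gain = ad_param(matrix(0, 1L, 1L), "adj_gain"),
    Theta_m = ad_param(th_m, "Theta_m"),
    Theta_p = ad_param(th_p, "Theta_p"),
    alpha_logit = ad_param(matrix(stats::qlogis(cfg$fusion$alpha_init),
                                  1L, 1L), "alpha_logit"),
    Wg = ad_param(ph_g$W, "Wg"), bg = ad_param(ph_g$b, "bg"),
    Ws = ad_param(ph_s$W, "Ws"), bs = ad_param(ph_s$b, "bs"),
    Wf = ad_param(fl$W, "Wf"), bf = ad_param(fl$b, "bf"),
    Wh = ad_param(ah$W, "Wh"), bh = ad_param(ah$b, "bh")
  )
  model <- list(config = cfg, embedder = embedder, pl = pl,
                gat_out = gat_out, s_width = s_width, feat_w = feat_w,
                history = NULL)
  class(model) <- "cmhs_model"
  model
}

# Flatten the (possibly const-wrapped) parameter tree into a list
.flatten_params <- function(pl) {
  out <- list()
  for (nm in names(pl)) {
    p <- pl[[nm]]
    if (nm == "gat") {
      for (h in p) out <- c(out, list(h$W, h$a1, h$a2))
    } else if (nm == "cross") {
      out <- c(out, list(p$W_m, p$W_p, p$a1, p$a2))
    } else out <- c(out, list(p))
  }
  out
}

#' List of trainable parameter nodes of a model
#' @param model `cmhs_model`
#' @export
model_parameters <- function(model) .flatten_params(model$pl)

# Const-wrapped copy of the parameter tree (evaluation mode: no tape)
.pl_as_const <- function(pl) {
  wrap <- function(x) {
    if (is.environment(x)) return(ad_const(x$val))
    lapply(x, wrap)
  }
  wrap(pl)
}

#' Precompute per-allele and per-peptide model inputs
#'
#' Per allele: BLOSUM and embedder features, contact adjacency, GNM
#' B-factors and the derived cross-edge noise sigmas. Per distinct
#' peptide: features padded to length 12 with a pad mask.
#' @param model `cmhs_model`
#' @param dataset `cmhs_dataset`
#' @return cache list (`mhc`, `pep`)
#' @export
build_cache <- function(model, dataset) {
  cfg <- model$config
  mhc <- list()
  for (id in unique(dataset$table$mhc_id)) {
    seq <- dataset$mhc_seqs[[id]]
    coords <- dataset$coords[[id]]
    Xmb <- blosum50_encode(seq)
    Xme <- embed_sequence(seq, model$embedder)
    A_mm <- contact_adjacency(coords, cfg$structure$contact_threshold)
    bfac <- gnm_bfactor(gnm_kirchhoff(A_mm))
    sigma <- sigma_from_bfactor(bfac, cfg$adj_noise$sigma_min,
                                cfg$adj_noise$sigma_max, cfg$adj_noise$k)
    Xm <- cbind(Xme, Xmb)
    mhc[[id]] <- list(Xm = Xm, Xmb = Xmb, A_mm = A_mm,
                      bfac = bfac, sigma = sigma,
                      pseudo = .pseudo_for(dataset, id),
                      L = nchar(seq),
                      l0m = matrix(apply(Xm, 2L, max), 1L))
  }
  pep <- list()
  for (p in unique(dataset$table$peptide)) {
    len <- nchar(p)
    Xpb <- blosum50_encode(p, 12L)
    Xpe <- embed_sequence(p, model$embedder, target_length = 12L)
    mask <- c(rep(1L, len), rep(0L, 12L - len))
    pep[[p]] <- list(Xp = cbind(Xpe, Xpb), Xpb = Xpb, mask = mask,
                     maskmat = matrix(mask, 12L, model$feat_w), len = len)
  }
  list(mhc = mhc, pep = pep)
}

# Allele-level subgraph of the forward pass: everything that does not
# depend on the peptide (the MHC CNN track of the pyramid, the GAT, and
# the MHC-side cross-attention term) is built once per allele per batch
# and shared across that batch's samples; the autodiff DAG accumulates
# the gradients from all consumers before running the shared nodes'
# adjoints, so sharing is exact.
.mhc_shared <- function(pl, cm, cfg) {
  out <- list(l0m = ad_const(cm$l0m))
  c1m <- ad_relu(ad_conv1d(ad_const(cm$Xm), pl$W1m, pl$b1m,
                           cfg$cnn$kernel_m))
  c2m <- ad_relu(ad_conv1d(c1m, pl$W2m, pl$b2m, cfg$cnn$kernel_m))
  out$p1m <- ad_maxpool_masked(c1m)
  out$p2m <- ad_maxpool_masked(c2m)
  if (cfg$variant != "sequence_only") {
    gat <- .gat_forward(ad_const(cm$Xmb), cm$A_mm, pl$gat,
                        cfg$gat$slope, cfg$gat$combine)
    out$H <- gat$H
    out$f1 <- ad_matmul(ad_matmul(gat$H, pl$cross$W_m), pl$cross$a1)
  }
  out
}

# Peptide-level subgraph: peptide CNN track and cross-attention peptide
# term. In training mode the noise draw makes it sample-specific; in
# evaluation mode it is shared per distinct peptide.
.pep_shared <- function(pl, cp, cfg, training) {
  Xp <- ad_const(cp$Xp)
  if (training && cfg$noise$enabled) {
    z <- matrix(stats::rnorm(length(cp$Xp)), nrow(cp$Xp))
    eps <- ad_add(ad_mul(ad_const(z), ad_exp(pl$noise_log_sigma)),
                  pl$noise_mu)
    Xp <- ad_add(Xp, ad_cmul(eps, cp$maskmat))
  }
  c1p <- ad_relu(ad_conv1d(Xp, pl$W1p, pl$b1p, cfg$cnn$kernel_p))
  out <- list(p0p = ad_maxpool_masked(Xp, cp$mask),
              p1p = ad_maxpool_masked(c1p, cp$mask))
  if (cfg$variant != "sequence_only") {
    out$f2 <- ad_matmul(ad_matmul(ad_const(cp$Xpb), pl$cross$W_p),
                        pl$cross$a2)
  }
  out
}

# Core of one pMHC pair given the shared allele/peptide nodes. Returns
# list(S = 1 x s_width pyramid node, zg = 1 x gcn_width graph node).
# Must run inside a seeded RNG context when training = TRUE.
.pair_core <- function(pl, cm, sh, pp, cp, cfg, training) {
  S_final <- ad_cbind(sh$l0m, pp$p0p, sh$p1m, pp$p1p, sh$p2m, pp$p1p)
  if (cfg$variant == "sequence_only") {
    return(list(S = S_final, zg = ad_const(matrix(0, 1L, cfg$gcn$width))))
  }
  cand <- matrix(0, cm$L, 12L)
  cand[cm$pseudo, seq_len(cp$len)] <- 1
  scores <- ad_add(ad_matmul(sh$f1, ad_const(matrix(1, 1L, 12L))),
                   ad_matmul(ad_const(matrix(1, cm$L, 1L)),
                             ad_t(pp$f2)))
  E <- ad_softmax_row(ad_leaky_relu(scores, cfg$cross$slope), cand)
  sel <- topk_extract(ad_value(E), cfg$topk$k, candidates = cand)
  selmask <- matrix(0, cm$L, 12L)
  if (nrow(sel$E_sub)) selmask[cbind(sel$E_sub$m, sel$E_sub$p)] <- 1
  A <- ad_cmul(E, selmask)
  if (training && cfg$adj_noise$enabled) {
    p <- 12L
    rowm <- ad_matmul(A, ad_const(matrix(1 / p, p, 1L)))
    center <- ad_sub(A, ad_matmul(rowm, ad_const(matrix(1, 1L, p))))
    mu <- ad_mul(center, pl$adj_gain)
    zs <- matrix(stats::rnorm(cm$L * p), cm$L) * cm$sigma
    A <- ad_cadd(ad_add(A, mu), zs)
  }
  Zmp <- .gcn_forward(ad_const(cp$Xpb), A, pl$Theta_m, cfg$gcn$activation)
  Zpm <- .gcn_forward(sh$H, ad_t(A), pl$Theta_p, cfg$gcn$activation)
  vsub <- integer(cm$L)
  vsub[sel$V_sub] <- 1L
  if (!any(vsub)) vsub <- NULL
  alpha <- ad_sigmoid(pl$alpha_logit)
  one_m <- ad_cadd(ad_cmul(alpha, -1), 1)
  zg <- ad_add(ad_mul(ad_meanpool_masked(Zmp, vsub), alpha),
               ad_mul(ad_meanpool_masked(Zpm, cp$mask), one_m))
  list(S = S_final, zg = zg)
}

# Batched head layers: projections, fusion, affinity head. Returns
# list(pred = B x 1 node, Hg, Hs = B x width nodes).
.heads_batch <- function(pl, Sb, zgb) {
  Hs <- ad_layernorm_row(ad_relu(ad_add(ad_matmul(Sb, pl$Ws), pl$bs)))
  Hg <- ad_layernorm_row(ad_relu(ad_add(ad_matmul(zgb, pl$Wg), pl$bg)))
  zf <- ad_add(ad_matmul(ad_cbind(Hg, Hs), pl$Wf), pl$bf)
  pred <- ad_sigmoid(ad_add(ad_matmul(zf, pl$Wh), pl$bh))
  list(pred = pred, Hg = Hg, Hs = Hs)
}

# Forward over a set of rows. Returns prediction node and loss pieces.
.forward_batch <- function(pl, cache, table, rows, cfg, training) {
  Ss <- vector("list", length(rows))
  zgs <- vector("list", length(rows))
  shared_m <- list()
  shared_p <- list()
  for (i in seq_along(rows)) {
    r <- rows[i]
    id <- table$mhc_id[r]
    pepid <- table$peptide[r]
    if (is.null(shared_m[[id]])) {
      shared_m[[id]] <- .mhc_shared(pl, cache$mhc[[id]], cfg)
    }
    pp <- if (training) {
      .pep_shared(pl, cache$pep[[pepid]], cfg, TRUE)
    } else {
      if (is.null(shared_p[[pepid]])) {
        shared_p[[pepid]] <- .pep_shared(pl, cache$pep[[pepid]], cfg,
                                         FALSE)
      }
      shared_p[[pepid]]
    }
    core <- .pair_core(pl, cache$mhc[[id]], shared_m[[id]], pp,
                       cache$pep[[pepid]], cfg, training)
    Ss[[i]] <- core$S
    zgs[[i]] <- core$zg
  }
  heads <- .heads_batch(pl, do.call(ad_rbind, Ss), do.call(ad_rbind, zgs))
  predb <- heads$pred
  targets <- matrix(table$affinity[rows], ncol = 1L)
  d <- ad_cadd(predb, -targets)
  mse <- ad_mean(ad_mul(d, d))
  beta <- cfg$loss$beta_cont
  if (beta > 0 && length(rows) > 1L && cfg$variant != "sequence_only") {
    B <- length(rows)
    Hgb <- ad_l2norm_row(heads$Hg)
    Hsb <- ad_l2norm_row(heads$Hs)
    Sim <- ad_cmul(ad_matmul(Hgb, ad_t(Hsb)), 1 / cfg$contrastive$tau)
    dmask <- diag(B)
    pos <- ad_sum(ad_cmul(ad_cadd(ad_cmul(Sim, -1), 1), dmask))
    neg <- ad_sum(ad_cmul(ad_relu(ad_cadd(Sim, -cfg$contrastive$margin)),
                          1 - dmask))
    cont <- ad_cmul(ad_add(pos, neg), 1 / (B * B))
  } else {
    cont <- ad_const(matrix(0, 1L, 1L))
  }
  total <- ad_add(ad_cmul(mse, cfg$loss$lambda), ad_cmul(cont, beta))
  list(total = total, mse = ad_value(mse)[1L],
       contrastive = ad_value(cont)[1L], preds = ad_value(predb)[, 1L])
}

#' Train a model on a pMHC dataset
#'
#' Seeded end to end: data shuffling, noise draws and parameter
#' initialization all derive from `config$seed`. Noise layers are active
#' only in training mode; the per-epoch validation loss is computed in
#' evaluation mode on a held-out fraction of the data.
#'
#' @param dataset `cmhs_dataset`
#' @param config configuration list; see [cmhs_config()]
#' @param quiet suppress per-epoch progress
#' @return trained `cmhs_model` with a `history` data.frame (epoch,
#'   train_loss, val_loss, mse, contrastive) and `val_rows` (indices of
#'   the held-out samples)
#' @export
train <- function(dataset, config = cmhs_config(), quiet = TRUE) {
  stopifnot(inherits(dataset, "cmhs_dataset"))
  if (nrow(dataset$table) < 2L) {
    cmhs_stop("dataset must contain at least 2 pairs",
              "cmhs_validation_error")
  }
  model <- cmhs_model(config)
  cfg <- model$config
  cache <- build_cache(model, dataset)
  n <- nrow(dataset$table)
  n_val <- max(0L, floor(cfg$train$val_fraction * n))
  val_rows <- if (n_val > 0L) {
    with_seed(derive_seed(cfg$seed, "valsplit"), sample.int(n, n_val))
  } else integer(0)
  train_rows <- setdiff(seq_len(n), val_rows)
  params <- .flatten_params(model$pl)
  opt <- NULL
  hist <- vector("list", cfg$train$epochs)
  for (epoch in seq_len(cfg$train$epochs)) {
    order_rows <- with_seed(derive_seed(cfg$seed, paste0("shuffle", epoch)), {
      rows <- sample(train_rows)
      if (isTRUE(cfg$train$group_by_allele)) {
        # group shuffled rows by allele (allele blocks in shuffled order)
        # so batches share per-allele computation
        blocks <- split(rows, dataset$table$mhc_id[rows])
        rows <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
      }
      rows
    })
    batches <- split(order_rows,
                     ceiling(seq_along(order_rows) / cfg$train$batch_size))
    ep_loss <- 0; ep_mse <- 0; ep_cont <- 0
    for (b in seq_along(batches)) {
      rows <- batches[[b]]
      ad_tape_reset()
      res <- with_seed(derive_seed(cfg$seed, paste0("noise", epoch, "_", b)),
                       .forward_batch(model$pl, cache, dataset$table, rows,
                                      cfg, training = TRUE))
      loss_val <- ad_value(res$total)[1L]
      if (!is.finite(loss_val)) {
        cmhs_stop(sprintf(
          "non-finite loss %.3g at epoch %d batch %d (rows %s)",
          loss_val, epoch, b, paste(utils::head(rows, 5L), collapse = ",")),
          "cmhs_training_error")
      }
      ad_zero_grads(params)
      ad_backward(res$total)
      opt <- adamw_step(params, opt, lr = cfg$train$lr,
                        weight_decay = cfg$train$weight_decay)
      w <- length(rows) / length(order_rows)
      ep_loss <- ep_loss + loss_val * w
      ep_mse <- ep_mse + res$mse * w
      ep_cont <- ep_cont + res$contrastive * w
    }
    val_loss <- NA_real_
    if (length(val_rows) > 1L) {
      ad_tape_reset()
      plc <- .pl_as_const(model$pl)
      vres <- .forward_batch(plc, cache, dataset$table, val_rows, cfg,
                             training = FALSE)
      val_loss <- ad_value(vres$total)[1L]
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val_loss, mse = ep_mse,
                                contrastive = ep_cont)
    if (!quiet) message(sprintf("epoch %3d  train %.5f  val %s", epoch,
                                ep_loss, format(val_loss, digits = 5)))
  }
  model$history <- do.call(rbind, hist)
  model$val_rows <- val_rows
  model$cache <- cache
  model$table <- dataset$table
  model
}

#' Predict normalized affinities for pMHC pairs
#'
#' Evaluation mode: both noise layers are identity maps.
#' @param object trained `cmhs_model`
#' @param newdata `cmhs_dataset` (or NULL to reuse the training cache)
#' @param rows optional row subset of the affinity table
#' @param ... unused
#' @return numeric vector of predicted affinities in (0, 1)
#' @export
predict.cmhs_model <- function(object, newdata = NULL, rows = NULL, ...) {
  cache <- if (is.null(newdata)) {
    object$cache %||% cmhs_stop("no cache; supply newdata",
                                "cmhs_validation_error")
  } else build_cache(object, newdata)
  table <- if (is.null(newdata)) object$table else newdata$table
  if (is.null(rows)) rows <- seq_len(nrow(table))
  preds <- numeric(length(rows))
  chunks <- split(seq_along(rows), ceiling(seq_along(rows) / 512L))
  for (ch in chunks) {
    ad_tape_reset()
    plc <- .pl_as_const(object$pl)
    res <- .forward_batch(plc, cache, table, rows[ch], object$config,
                          training = FALSE)
    preds[ch] <- res$preds
  }
  preds
}

#' @export
print.cmhs_model <- function(x, ...) {
  np <- sum(vapply(.flatten_params(x$pl), function(p) length(p$val), 1L))
  cat(sprintf("<cmhs_model (%s, %s embedder w=%d): %d parameters%s>\n",
              x$config$variant, x$config$embedder$kind,
              x$config$embedder$width, np,
              if (is.null(x$history)) ", untrained" else ", trained"))
  invisible(x)
}

#' K-fold cross-validation
#'
#' Seeded disjoint folds; every sample is validated exactly once. Each
#' fold trains a fresh model on the remaining folds and evaluates on the
#' held-out fold.
#' @param dataset `cmhs_dataset`
#' @param config configuration list
#' @param quiet suppress progress
#' @return list with `folds` (per-fold `cmhs_metrics`), `mean` and `sd`
#'   across folds
#' @export
cross_validate <- function(dataset, config = cmhs_config(), quiet = TRUE) {
  cfg <- merge_config(cmhs_config(), config)
  n <- nrow(dataset$table)
  k <- cfg$train$folds
  if (k > n) cmhs_stop("more folds than samples", "cmhs_config_error")
  assign_fold <- with_seed(derive_seed(cfg$seed, "folds"),
                           sample(rep_len(seq_len(k), n)))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(assign_fold == f)
    sub <- dataset
    sub$table <- dataset$table[-hold, , drop = FALSE]
    model <- train(sub, cfg, quiet = quiet)
    eval_ds <- dataset
    eval_ds$table <- dataset$table[hold, , drop = FALSE]
    preds <- predict(model, eval_ds)
    reports[[f]] <- metric_report(preds, eval_ds$table)
    if (!quiet) message(sprintf("fold %d: SRCC %.3f", f,
                                reports[[f]]$srcc))
  }
  vals <- sapply(reports, function(r) unlist(r[c("srcc", "pcc", "auroc",
                                                 "acc")]))
  list(folds = reports, mean = rowMeans(vals),
       sd = apply(vals, 1L, stats::sd), fold_assignment = assign_fold)
}

#' Save a model checkpoint (single JSON file)
#'
#' Stores the configuration snapshot, every named parameter tensor and a
#' fingerprint of the BLOSUM50 fixture used at training time.
#' @param model `cmhs_model`
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  unwrap <- function(x) {
    if (is.environment(x)) {
      return(list(.tensor = TRUE, dim = dim(x$val), data = as.numeric(x$val)))
    }
    lapply(x, unwrap)
  }
  obj <- list(package = "cmhs", format = 1L,
              blosum_fingerprint = blosum50_fingerprint(),
              config = model$config, params = unwrap(model$pl))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file
#' @return `cmhs_model` with restored parameters
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$package, "cmhs")) {
    cmhs_stop("not a cmhs checkpoint", "cmhs_parse_error")
  }
  if (!identical(obj$blosum_fingerprint, blosum50_fingerprint())) {
    warning("checkpoint was trained against a different BLOSUM50 fixture")
  }
  cfg <- obj$config
  cfg$cnn$channels <- cfg$cnn$channels %||% NULL
  model <- cmhs_model(cfg)
  restore <- function(node, stored, path) {
    if (is.environment(node)) {
      v <- matrix(unlist(stored$data), stored$dim[[1L]], stored$dim[[2L]])
      if (!identical(dim(v), dim(node$val))) {
        cmhs_stop(sprintf(
          "checkpoint tensor '%s' is %dx%d but the model expects %dx%d",
          path, nrow(v), ncol(v), nrow(node$val), ncol(node$val)),
          "cmhs_dimension_error")
      }
      node$val <- v
      return(invisible(NULL))
    }
    keys <- names(node) %||% seq_along(node)
    for (nm in keys) restore(node[[nm]], stored[[nm]],
                             paste0(path, ".", nm))
  }
  restore(model$pl, obj$params, "params")
  model
}

#' Write a training history to CSV
#' @param history data.frame from a trained model
#' @param path output file
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
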