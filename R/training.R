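# Losses, the contrastive perturbation, and the optimization loop.

#' Sign-preserving random feature perturbation
#'
#' Returns `h + |eps| * sign(h)` with `eps` drawn componentwise from
#' `Uniform(0, eps_max)` under `seed`; `sign(0) = 0`, so zero entries
#' stay zero and no component changes sign or moves by more than
#' `eps_max`.  This is the noise used to build the second (perturbed)
#' view for contrastive training.
#'
#' @param h numeric matrix or vector.
#' @param eps_max nonnegative perturbation bound.
#' @param seed integer seed.
#' @return perturbed copy of `h`.
#' @export
perturb_features <- function(h, eps_max, seed = 1) {
  stopifnot(eps_max >= 0)
  with_seed(seed, h + .sign_noise(h, eps_max))
}

#' InfoNCE contrastive loss
#'
#' `-(1/M) sum_m log( exp(cos(z_m, z'_m)/tau) /
#'   sum_{m'} exp(cos(z_m, z'_{m'})/tau) )` over paired representation
#' matrices; cos is cosine similarity.
#'
#' @param Z,Zp M x d matrices of paired views (row m of `Zp` is the
#'   perturbed view of row m of `Z`).
#' @param tau temperature (default 0.5).
#' @return nonnegative scalar loss.
#' @export
info_nce <- function(Z, Zp, tau = 0.5) {
  Z <- as.matrix(Z); Zp <- as.matrix(Zp)
  stopifnot(nrow(Z) == nrow(Zp), ncol(Z) == ncol(Zp), nrow(Z) >= 1)
  nz <- sqrt(rowSums(Z^2)); np <- sqrt(rowSums(Zp^2))
  if (any(nz == 0) || any(np == 0)) stop("zero-norm representation row")
  S <- tcrossprod(Z / nz, Zp / np) / tau
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  -mean(diag(S) - lse)
}

#' Binary cross-entropy loss
#'
#' Mean over all protein-term cells of
#' `-(y log yhat + (1-y) log(1-yhat))`, with predictions clipped away
#' from 0 and 1 by 1e-12.
#'
#' @param y binary M x C matrix of true labels.
#' @param yhat M x C matrix of predicted probabilities in (0, 1).
#' @return nonnegative scalar loss.
#' @export
bce_loss <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch between y and yhat")
  p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Weighted total training loss
#'
#' @param l_sup supervised (BCE) loss.
#' @param l_reg contrastive (InfoNCE) loss.
#' @param weights length-2 weights, default `c(1, 1)`.
#' @return `weights[1] * l_sup + weights[2] * l_reg`.
#' @export
total_loss <- function(l_sup, l_reg, weights = c(1, 1)) {
  weights[1] * l_sup + weights[2] * l_reg
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size proteins per optimization step.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before
#'   stopping.
#' @param tau InfoNCE temperature.
#' @param eps_max contrastive perturbation bound.
#' @param seed seed controlling shuffling, dropout and perturbations.
#' @param loss_weights supervised / contrastive loss weights.
#' @param clip_norm global gradient-norm clip.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64,
                         max_epochs = 100, patience = 5, tau = 0.5,
                         eps_max = 0.1, seed = 1, loss_weights = c(1, 1),
                         clip_norm = 1.0) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs, tau > 0, eps_max >= 0)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, tau = tau,
                 eps_max = eps_max, seed = seed,
                 loss_weights = loss_weights, clip_norm = clip_norm),
            class = "train_config")
}

# tape version of the two losses (values identical to the numeric ones)
.bce_tape <- function(Ynode, y) {
  # Ynode: logits node (M x C).  BCE via the numerically stable
  # softplus form: mean(softplus(x) - y*x)
  yv <- as.matrix(y)
  x <- Ynode
  # softplus(x) = log(1 + exp(x)) computed as max(x,0)+log1p(exp(-|x|))
  xp <- ad_relu(x)
  xn <- ad_relu(ad_scale(x, -1))
  sp <- ad_add(xp, ad_log(ad_add_const(ad_exp(ad_scale(ad_add(xp, xn), -1)),
                                       1)))
  ad_mean(ad_sub(sp, ad_mul(x, yv)))
}

.infonce_tape <- function(Z, Zp, tau) {
  M <- nrow(ad_val(Z))
  one_d <- matrix(1, ncol(ad_val(Z)), 1L)
  nz <- ad_sqrt(ad_matmul(ad_mul(Z, Z), one_d), eps = 1e-12)
  np <- ad_sqrt(ad_matmul(ad_mul(Zp, Zp), one_d), eps = 1e-12)
  Zn <- ad_mul_bcol(Z, ad_recip(nz))
  Zpn <- ad_mul_bcol(Zp, ad_recip(np))
  S <- ad_scale(ad_matmul_bt(Zn, Zpn), 1 / tau)
  P <- ad_softmax_rows(S)
  diag_mask <- diag(1, M)
  ad_scale(ad_sum(ad_mul(ad_log(P), diag_mask)), -1 / M)
}

#' Train a model with supervised + contrastive objectives
#'
#' Adam optimization of binary cross-entropy plus InfoNCE.  Each batch
#' runs one clean forward per protein (giving predictions and pooled
#' representations Z) and one perturbed forward (sign-preserving noise
#' injected into the lifted node features, giving Z'), and minimizes
#' `w1 * BCE + w2 * InfoNCE`.  Validation total loss is monitored with
#' early stopping; the best-validation parameters are returned.  All
#' randomness derives from `cfg$seed`.
#'
#' @param model a `gvp_model`.
#' @param graphs list of `residue_graph` objects.
#' @param labels binary matrix (length(graphs) x n_terms).
#' @param split list with integer indices `train` and `val`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best parameters) and `report` (class
#'   `train_report`: per-epoch train/val losses, best and stopping
#'   epoch, seed).
#' @export
train <- function(model, graphs, labels, split, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "gvp_model"))
  labels <- as.matrix(labels)
  if (length(split$train) == 0 || length(split$val) == 0) {
    stop("empty train or validation split")
  }
  w <- cfg$loss_weights
  params <- model$params
  opt <- .adam_init(params)
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  tr_loss <- val_loss <- numeric(0)
  stall <- 0L; stopping <- cfg$max_epochs
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(split$train)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      res <- .batch_loss(params, model$cfg, graphs[b],
                         labels[b, , drop = FALSE], cfg, w,
                         train_mode = TRUE, want_grad = TRUE)
      ep_loss <- ep_loss + res$loss * length(b)
      params <- .adam_step(params, res$grads, opt, cfg$learning_rate,
                           cfg$clip_norm)
    }
    tr_loss <- c(tr_loss, ep_loss / length(ord))
    vres <- .batch_loss(params, model$cfg, graphs[split$val],
                        labels[split$val, , drop = FALSE], cfg, w,
                        train_mode = FALSE, want_grad = FALSE,
                        noise_seed = cfg$seed + 131071L)
    val_loss <- c(val_loss, vres$loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tr_loss[epoch], val_loss[epoch]))
    }
    if (vres$loss < best_val - 1e-9) {
      best_val <- vres$loss; best_params <- params; best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) { stopping <- epoch; break }
    }
    stopping <- epoch
  }
  model$params <- best_params
  report <- structure(list(train_loss = tr_loss, val_loss = val_loss,
                           best_epoch = best_epoch,
                           stopping_epoch = stopping, seed = cfg$seed),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(
    "<train_report> %d epoch(s), best epoch %d (val %.4f), seed %d\n",
    x$stopping_epoch, x$best_epoch,
    if (x$best_epoch > 0) x$val_loss[x$best_epoch] else NA, x$seed))
  invisible(x)
}

# forward (+ optional backward) over one batch of proteins
.batch_loss <- function(params, mcfg, graphs, y, cfg, w,
                        train_mode = TRUE, want_grad = TRUE,
                        noise_seed = NULL) {
  run <- function() {
    tape <- ad_tape()
    pl <- .param_leaves(tape, params)
    use_cl <- w[2] != 0
    fw <- .forward_batch(pl, mcfg, graphs, tape, train = train_mode)
    logit_rows <- lapply(fw, function(x) x$logits)
    z_rows <- lapply(fw, function(x) x$z)
    if (use_cl) {
      fwp <- .forward_batch(pl, mcfg, graphs, tape, train = train_mode,
                            perturb = cfg$eps_max)
      zp_rows <- lapply(fwp, function(x) x$z)
    }
    logits <- ad_rbind(logit_rows)
    l_sup <- .bce_tape(logits, y)
    loss <- ad_scale(l_sup, w[1])
    if (use_cl) {
      l_reg <- .infonce_tape(ad_rbind(z_rows), ad_rbind(zp_rows), cfg$tau)
      loss <- ad_add(loss, ad_scale(l_reg, w[2]))
    }
    if (want_grad) ad_backward(loss)
    list(loss = ad_val(loss)[1L],
         grads = if (want_grad) lapply(pl, function(nd) {
           if (is.null(nd$grad)) nd$val * 0 else nd$grad
         }) else NULL)
  }
  if (is.null(noise_seed)) run() else with_seed(noise_seed, run())
}

.adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

.adam_step <- function(params, grads, st, lr, clip_norm,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(clip_norm) && gn > clip_norm) {
    grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / corr1
    vhat <- st$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
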