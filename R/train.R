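adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, frozen = character(),
                      weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    upd <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    # decoupled weight decay on weight matrices only (not biases/gains)
    if (weight_decay > 0 && is.matrix(params[[nm]]) && !grepl("rel$", nm)) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# one-hot tensors for every pair in a manifest, as parallel lists
manifest_tensors <- function(manifest, genome, width) {
  enc_side <- function(chrom, start, end) {
    w <- standardize_window(tibble(chrom = chrom, start = start, end = end), width)
    purrr::pmap(
      list(w$chrom, w$start, w$end),
      function(c, s, e) one_hot_encode(genome_sequence(genome, c, s, e))
    )
  }
  list(
    left = enc_side(manifest$left_chrom, manifest$left_start, manifest$left_end),
    right = enc_side(manifest$right_chrom, manifest$right_start, manifest$right_end),
    label = as.integer(manifest$label == "positive")
  )
}

batch_forward_backward <- function(model, tensors, idx) {
  X_l <- do.call(rbind, tensors$left[idx])
  X_r <- do.call(rbind, tensors$right[idx])
  y <- tensors$label[idx]
  if (use_cpp_engine()) {
    res <- cpp_batch(model$params, cpp_dims(model$config, length(idx)),
      X_l, X_r, as.numeric(y), model$config$dropout, TRUE, TRUE, FALSE
    )
    return(list(loss = res$loss, grads = res$grads))
  }
  plan <- make_plan(model$config, length(idx))
  fwd <- etnet_forward_core(model, X_l, X_r, plan, train = TRUE)
  eps <- 1e-12
  loss <- -mean(y * log(fwd$prob + eps) + (1 - y) * log(1 - fwd$prob + eps))
  dlogit <- (fwd$prob - y) / length(idx)
  bwd <- etnet_backward_core(model, fwd, plan, dlogit)
  list(loss = loss, grads = bwd$grads)
}

predict_tensors <- function(model, tensors, idx = seq_along(tensors$label),
                            batch_size = 100L) {
  out <- numeric(length(idx))
  for (chunk in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    ii <- idx[chunk]
    X_l <- do.call(rbind, tensors$left[ii])
    X_r <- do.call(rbind, tensors$right[ii])
    if (use_cpp_engine()) {
      res <- cpp_batch(model$params, cpp_dims(model$config, length(ii)),
        X_l, X_r, NULL, 0, FALSE, FALSE, FALSE
      )
      out[chunk] <- res$prob
    } else {
      plan <- make_plan(model$config, length(ii))
      out[chunk] <- etnet_forward_core(model, X_l, X_r, plan)$prob
    }
  }
  out
}

#' Train the sequence-pair classifier
#'
#' Minimizes binary cross-entropy with the Adam optimizer (defaults: learning
#' rate 1e-5, 50 epochs, batch size 100). The manifest's `train` split is used
#' for gradient updates and the `validation` split for per-epoch monitoring;
#' the checkpoint with the best validation AUC is retained. With
#' `patience` set, training stops early after that many epochs without
#' validation-AUC improvement. Fully seeded: the same seed reproduces the
#' same trained model.
#'
#' @param model An `etnet_model` from [build_model()].
#' @param manifest A pair manifest with a `split` column.
#' @param genome An `eei_genome`.
#' @param lr Learning rate (default 1e-5).
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 100).
#' @param patience Early-stopping patience in epochs on validation AUC;
#'   `NULL` (default) disables early stopping.
#' @param weight_decay Decoupled weight-decay coefficient applied to weight
#'   matrices (not biases or layer-norm gains); default 0.
#' @param restarts Number of random initializations to probe (default 1, no
#'   restarts). With `restarts > 1`, each candidate (the supplied model plus
#'   `restarts - 1` re-initializations with derived seeds) is trained for
#'   `probe_epochs`; the candidate with the best monitored value is then
#'   trained from scratch for the full schedule. Small networks on hard
#'   tasks occasionally start in the constant-predictor basin and never
#'   escape; probing avoids reporting such runs.
#' @param probe_epochs Probe length in epochs when `restarts > 1`
#'   (default 20).
#' @param seed Integer seed for batch shuffling and dropout.
#' @param frozen_groups Character vector of parameter groups to exclude from
#'   updates (see [finetune_selective()]).
#' @param verbose Print per-epoch progress.
#' @return A list of class `etnet_fit`: `model` (best-validation checkpoint),
#'   `history` (tibble of per-epoch loss and validation metrics),
#'   `best_epoch`, `val_auc`.
#' @export
etnet_train <- function(model, manifest, genome, lr = 1e-5, epochs = 50L,
                        batch_size = 100L, patience = NULL, seed = 1L,
                        weight_decay = 0, frozen_groups = character(),
                        verbose = FALSE, restarts = 1L, probe_epochs = 20L) {
  stopifnot(inherits(model, "etnet_model"), "split" %in% names(manifest))
  if (restarts > 1L) {
    cands <- vector("list", restarts)
    seeds <- integer(restarts)
    scores <- numeric(restarts)
    for (r in seq_len(restarts)) {
      cands[[r]] <- if (r == 1L) {
        model
      } else {
        build_model(model$config, seed = derive_seed(seed, paste0("restart", r)))
      }
      seeds[r] <- derive_seed(seed, paste0("probe", r))
      probe <- etnet_train(cands[[r]], manifest, genome,
        lr = lr, epochs = probe_epochs, batch_size = batch_size,
        patience = NULL, seed = seeds[r], weight_decay = weight_decay,
        frozen_groups = frozen_groups, verbose = FALSE, restarts = 1L
      )
      scores[r] <- probe$val_auc
      if (verbose) {
        inform(sprintf("restart %d probe value %.4f", r, probe$val_auc))
      }
    }
    best_r <- which.max(scores)
    return(etnet_train(cands[[best_r]], manifest, genome,
      lr = lr, epochs = epochs, batch_size = batch_size, patience = patience,
      seed = seeds[best_r], weight_decay = weight_decay,
      frozen_groups = frozen_groups, verbose = verbose, restarts = 1L
    ))
  }
  train_idx_all <- which(manifest$split == "train")
  val_idx <- which(manifest$split == "validation")
  if (length(train_idx_all) == 0L) abort("empty training split")
  tensors <- manifest_tensors(manifest, genome, model$config$seq_len)
  frozen <- names(model$groups)[model$groups %in% frozen_groups]
  state <- adam_init(model$params)
  history <- list()
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  stale <- 0L
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx_all)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        res <- batch_forward_backward(model, tensors, bidx)
        upd <- adam_step(model$params, res$grads, state, lr, frozen,
          weight_decay
        )
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + res$loss * length(bidx)
      }
      ep_loss <- ep_loss / length(ord)
      val_auc <- NA_real_
      if (length(val_idx) > 0L) {
        vp <- predict_tensors(model, tensors, val_idx, batch_size)
        vl <- tensors$label[val_idx]
        val_auc <- if (length(unique(vl)) == 2L) auc_rank(vl, vp) else NA_real_
      }
      history[[ep]] <- tibble(epoch = ep, loss = ep_loss, val_auc = val_auc)
      if (verbose) {
        inform(sprintf("epoch %d loss %.4f val_auc %.4f", ep, ep_loss, val_auc))
      }
      monitored <- if (is.na(val_auc)) -ep_loss else val_auc
      if (monitored > best$auc) {
        best <- list(auc = monitored, params = model$params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (!is.null(patience) && stale >= patience) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  structure(
    list(
      model = model, history = bind_rows(history),
      best_epoch = best$epoch, val_auc = best$auc
    ),
    class = "etnet_fit"
  )
}

#' @export
print.etnet_fit <- function(x, ...) {
  cat(
    "<etnet_fit> ", nrow(x$history), " epoch(s), best epoch ", x$best_epoch,
    ", monitored value ", signif(x$val_auc, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.etnet_fit <- function(x, ...) x$history

#' @export
glance.etnet_fit <- function(x, ...) {
  tibble(
    epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    best_val_auc = x$val_auc,
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' Selective fine-tuning with a frozen Transformer encoder
#'
#' Adapts a trained model to a new dataset while keeping every
#' Transformer-encoder parameter bitwise unchanged: only the convolutional
#' layers, the input MLP and the output heads are updated. Defaults follow
#' the transfer protocol: Adam, learning rate 1e-4, 30 epochs, early stopping
#' with patience 5 on validation AUC.
#'
#' @param model A trained `etnet_model`.
#' @param manifest Pair manifest for the target dataset (with `split`).
#' @param genome Target `eei_genome`.
#' @param lr Learning rate (default 1e-4).
#' @param epochs Maximum epochs (default 30).
#' @param patience Early-stopping patience (default 5).
#' @inheritParams etnet_train
#' @return An `etnet_fit` (see [etnet_train()]).
#' @export
finetune_selective <- function(model, manifest, genome, lr = 1e-4,
                               epochs = 30L, patience = 5L, batch_size = 100L,
                               seed = 1L, verbose = FALSE) {
  if (!"encoder" %in% model$groups) {
    abort("model lacks an identifiable encoder parameter group")
  }
  etnet_train(model, manifest, genome,
    lr = lr, epochs = epochs, batch_size = batch_size, patience = patience,
    seed = seed, frozen_groups = "encoder", verbose = verbose
  )
}

#' Score every pair of a manifest with a trained model
#'
#' @param model A trained `etnet_model`.
#' @param manifest A pair manifest.
#' @param genome An `eei_genome`.
#' @param split Optional split name to restrict scoring to.
#' @param batch_size Prediction batch size.
#' @return The (restricted) manifest with a `score` column appended.
#' @export
predict_manifest <- function(model, manifest, genome, split = NULL,
                             batch_size = 100L) {
  if (!is.null(split)) {
    manifest <- manifest[manifest$split %in% split, , drop = FALSE]
  }
  tensors <- manifest_tensors(manifest, genome, model$config$seq_len)
  manifest$score <- predict_tensors(model, tensors,
    batch_size = batch_size
  )
  manifest
}
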