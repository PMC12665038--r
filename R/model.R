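#' Model configuration for the sequence-pair classifier
#'
#' Hyperparameters of the two-branch CNN + Transformer-encoder architecture.
#' Each branch one-hot encodes a `seq_len` bp window, scans it with
#' `conv_channels` 1-D convolutional kernels of length `conv_kernel`
#' (length-preserving, zero-padded), max-pools by `pool_factor` (the default
#' 2000 -> 500 positions), and passes each pooled position vector through a
#' single-layer MLP into a `mlp_hidden`-dimensional token. Tokens from both
#' branches are concatenated along the position axis and processed by
#' `n_encoder_layers` Transformer encoder blocks (multi-head self-attention
#' with a learned relative-position bias, position-wise feed-forward network,
#' residual connections and layer normalization). Two prediction heads pool
#' the left-branch and right-branch tokens respectively; their logits are
#' averaged and squashed through a sigmoid.
#'
#' @param seq_len Input window length in bp (default 2000).
#' @param conv_channels Number of convolutional kernels (default 128).
#' @param conv_kernel Kernel length in bp (odd; default 9).
#' @param pool_factor Max-pooling factor; `seq_len` must be divisible by it
#'   (default 4).
#' @param mlp_hidden Token dimension after the single-layer MLP (default 512).
#' @param n_heads Attention heads (default 8).
#' @param d_value_total Total value dimension across heads (default 1024);
#'   must be divisible by `n_heads`.
#' @param d_qk_total Total key/query dimension across heads (default 1000);
#'   must be divisible by `n_heads`.
#' @param n_encoder_layers Number of encoder blocks (default 1).
#' @param ffn_dim Feed-forward inner dimension (default `4 * d_value_total`).
#' @param dropout Dropout probability during training (default 0.1).
#' @param head_hidden Hidden width of each prediction head (default 256).
#' @param tie_conv Share convolution/MLP weights between the two branches
#'   (siamese, default `TRUE`) or keep per-branch copies.
#' @return An `etnet_config` list.
#' @export
etnet_config <- function(seq_len = 2000L, conv_channels = 128L,
                         conv_kernel = 9L, pool_factor = 4L,
                         mlp_hidden = 512L, n_heads = 8L,
                         d_value_total = 1024L, d_qk_total = 1000L,
                         n_encoder_layers = 1L, ffn_dim = 4L * d_value_total,
                         dropout = 0.1, head_hidden = 256L, tie_conv = TRUE) {
  cfg <- list(
    seq_len = as.integer(seq_len), conv_channels = as.integer(conv_channels),
    conv_kernel = as.integer(conv_kernel), pool_factor = as.integer(pool_factor),
    mlp_hidden = as.integer(mlp_hidden), n_heads = as.integer(n_heads),
    d_value_total = as.integer(d_value_total), d_qk_total = as.integer(d_qk_total),
    n_encoder_layers = as.integer(n_encoder_layers), ffn_dim = as.integer(ffn_dim),
    dropout = dropout, head_hidden = as.integer(head_hidden), tie_conv = tie_conv
  )
  if (cfg$d_qk_total %% cfg$n_heads != 0L) {
    abort("invalid config: d_qk_total must be divisible by n_heads")
  }
  if (cfg$d_value_total %% cfg$n_heads != 0L) {
    abort("invalid config: d_value_total must be divisible by n_heads")
  }
  if (cfg$seq_len %% cfg$pool_factor != 0L) {
    abort("invalid config: seq_len must be divisible by pool_factor")
  }
  if (cfg$conv_kernel %% 2L != 1L) {
    abort("invalid config: conv_kernel must be odd")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    abort("invalid config: dropout must be in [0, 1)")
  }
  structure(cfg, class = "etnet_config")
}

n_tokens <- function(cfg) 2L * cfg$seq_len %/% cfg$pool_factor

#' Build a randomly initialized model
#'
#' Parameter initialization is reproducible from `seed` (Glorot-style scaled
#' normal weights, zero biases, unit layer-norm gains, zero relative-position
#' bias).
#'
#' @param config An [etnet_config()].
#' @param seed Integer seed for initialization.
#' @return An `etnet_model` object (config + named parameter list + parameter
#'   group labels used by selective fine-tuning).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "etnet_config"))
  cfg <- config
  Tm <- cfg$seq_len %/% cfg$pool_factor
  T2 <- 2L * Tm
  p <- list()
  grp <- character()
  add <- function(name, value, group) {
    p[[name]] <<- value
    grp[name] <<- group
  }
  with_seed(derive_seed(seed, "init"), {
    gl <- function(nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    }
    kin <- 4L * cfg$conv_kernel
    add("conv_w", gl(kin, cfg$conv_channels), "conv")
    add("conv_b", numeric(cfg$conv_channels), "conv")
    if (!cfg$tie_conv) {
      add("conv_w_r", gl(kin, cfg$conv_channels), "conv")
      add("conv_b_r", numeric(cfg$conv_channels), "conv")
    }
    add("mlp_w", gl(cfg$conv_channels, cfg$mlp_hidden), "input")
    add("mlp_b", numeric(cfg$mlp_hidden), "input")
    for (l in seq_len(cfg$n_encoder_layers)) {
      pre <- paste0("enc", l, "_")
      add(paste0(pre, "wq"), gl(cfg$mlp_hidden, cfg$d_qk_total), "encoder")
      add(paste0(pre, "bq"), numeric(cfg$d_qk_total), "encoder")
      add(paste0(pre, "wk"), gl(cfg$mlp_hidden, cfg$d_qk_total), "encoder")
      add(paste0(pre, "bk"), numeric(cfg$d_qk_total), "encoder")
      add(paste0(pre, "wv"), gl(cfg$mlp_hidden, cfg$d_value_total), "encoder")
      add(paste0(pre, "bv"), numeric(cfg$d_value_total), "encoder")
      add(paste0(pre, "wo"), gl(cfg$d_value_total, cfg$mlp_hidden), "encoder")
      add(paste0(pre, "bo"), numeric(cfg$mlp_hidden), "encoder")
      add(paste0(pre, "rel"), matrix(0, cfg$n_heads, 2L * T2 - 1L), "encoder")
      add(paste0(pre, "ln1_g"), rep(1, cfg$mlp_hidden), "encoder")
      add(paste0(pre, "ln1_b"), numeric(cfg$mlp_hidden), "encoder")
      add(paste0(pre, "ff_w1"), gl(cfg$mlp_hidden, cfg$ffn_dim), "encoder")
      add(paste0(pre, "ff_b1"), numeric(cfg$ffn_dim), "encoder")
      add(paste0(pre, "ff_w2"), gl(cfg$ffn_dim, cfg$mlp_hidden), "encoder")
      add(paste0(pre, "ff_b2"), numeric(cfg$mlp_hidden), "encoder")
      add(paste0(pre, "ln2_g"), rep(1, cfg$mlp_hidden), "encoder")
      add(paste0(pre, "ln2_b"), numeric(cfg$mlp_hidden), "encoder")
    }
    for (side in c("l", "r")) {
      add(paste0("head_", side, "_w"), gl(cfg$mlp_hidden, cfg$head_hidden), "head")
      add(paste0("head_", side, "_b"), numeric(cfg$head_hidden), "head")
      add(paste0("head_", side, "_v"), gl(cfg$head_hidden, 1L), "head")
      add(paste0("head_", side, "_c"), 0, "head")
    }
  })
  structure(
    list(config = cfg, params = p, groups = grp),
    class = "etnet_model"
  )
}

#' @export
print.etnet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1)))
  cfg <- x$config
  cat(
    "<etnet_model> seq_len=", cfg$seq_len, ", conv=", cfg$conv_channels,
    "x", cfg$conv_kernel, ", tokens=", n_tokens(cfg), ", heads=", cfg$n_heads,
    ", layers=", cfg$n_encoder_layers, ", params=", npar, "\n",
    sep = ""
  )
  invisible(x)
}

# index bookkeeping for a batch of B sequence pairs
make_plan <- function(cfg, B) {
  L <- cfg$seq_len
  k <- cfg$conv_kernel
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  P <- cfg$pool_factor
  Tm <- L %/% P
  T2 <- 2L * Tm
  base_p <- rep((0:(B - 1L)) * Lp, each = L)
  core_rows <- base_p + pad + seq_len(L)
  ic_rows <- lapply(seq_len(k), function(j) base_p + (j - 1L) + seq_len(L))
  # direct im2col without the padded copy: tap j reads input position
  # t + (j - 1 - pad); valid output positions t per sample
  base_x <- (0:(B - 1L)) * L
  ic_direct <- lapply(seq_len(k), function(j) {
    off <- j - 1L - pad
    t_lo <- max(1L, 1L - off)
    t_hi <- min(L, L - off)
    t <- seq.int(t_lo, t_hi)
    list(
      dst = rep(base_x, each = length(t)) + t,
      src = rep(base_x, each = length(t)) + t + off
    )
  })
  base_t <- rep((0:(B - 1L)) * T2, each = Tm)
  xl_rows <- base_t + seq_len(Tm)
  xr_rows <- base_t + Tm + seq_len(Tm)
  didx <- outer(seq_len(T2), seq_len(T2), function(t, s) s - t + T2)
  list(
    B = B, L = L, k = k, pad = pad, Lp = Lp, P = P, Tm = Tm, T2 = T2,
    core_rows = core_rows, ic_rows = ic_rows, ic_direct = ic_direct,
    xl_rows = xl_rows, xr_rows = xr_rows,
    grp_pool = rep(seq_len(B), each = Tm),
    didx = didx, didx_vec = as.vector(didx)
  )
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- cache$istd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

conv_branch_fwd <- function(params, cfg, plan, X, side) {
  use_r <- !cfg$tie_conv && side == "r"
  Wc <- if (use_r) params$conv_w_r else params$conv_w
  bc <- if (use_r) params$conv_b_r else params$conv_b
  IC <- matrix(0, plan$B * plan$L, 4L * plan$k)
  for (j in seq_len(plan$k)) {
    d <- plan$ic_direct[[j]]
    IC[d$dst, (j - 1L) * 4L + 1:4] <- X[d$src, ]
  }
  Hpre <- add_bias(IC %*% Wc, bc)
  relu_mask <- Hpre > 0
  H <- Hpre * relu_mask
  # max-pool in windows of P consecutive rows (windows never cross samples)
  nt <- plan$B * plan$Tm
  first <- seq.int(1L, plan$B * plan$L, by = plan$P)
  pool <- H[first, , drop = FALSE]
  amax <- matrix(0L, nt, cfg$conv_channels)
  for (j in seq_len(plan$P - 1L)) {
    Hj <- H[first + j, , drop = FALSE]
    better <- Hj > pool
    pool[better] <- Hj[better]
    amax[better] <- j
  }
  Mpre <- add_bias(pool %*% params$mlp_w, params$mlp_b)
  mlp_mask <- Mpre > 0
  M <- Mpre * mlp_mask
  list(
    M = M, IC = IC, relu_mask = relu_mask, pool = pool, amax = amax,
    mlp_mask = mlp_mask, first = first
  )
}

conv_branch_bwd <- function(params, cfg, plan, cache, dM, side,
                            want_input_grad = FALSE) {
  use_r <- !cfg$tie_conv && side == "r"
  Wc <- if (use_r) params$conv_w_r else params$conv_w
  dMpre <- dM * cache$mlp_mask
  dWm <- crossprod(cache$pool, dMpre)
  dbm <- colSums(dMpre)
  dpool <- dMpre %*% t(params$mlp_w)
  dH <- matrix(0, plan$B * plan$L, cfg$conv_channels)
  for (c in seq_len(cfg$conv_channels)) {
    rows <- cache$first + cache$amax[, c]
    dH[rows, c] <- dpool[, c]
  }
  dHpre <- dH * cache$relu_mask
  dWc <- crossprod(cache$IC, dHpre)
  dbc <- colSums(dHpre)
  out <- list(dWc = dWc, dbc = dbc, dWm = dWm, dbm = dbm)
  if (want_input_grad) {
    dIC <- dHpre %*% t(Wc)
    dX <- matrix(0, plan$B * plan$L, 4L)
    for (j in seq_len(plan$k)) {
      d <- plan$ic_direct[[j]]
      dX[d$src, ] <- dX[d$src, ] + dIC[d$dst, (j - 1L) * 4L + 1:4]
    }
    out$dX <- dX
  }
  out
}

dropout_mask <- function(n, m, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# full forward pass over a batch; X_l / X_r are (B*L) x 4 stacked one-hot
etnet_forward_core <- function(model, X_l, X_r, plan, train = FALSE,
                               keep_attention = FALSE) {
  cfg <- model$config
  p <- model$params
  H <- cfg$n_heads
  dk <- cfg$d_qk_total %/% H
  dv <- cfg$d_value_total %/% H
  T2 <- plan$T2
  B <- plan$B

  cb_l <- conv_branch_fwd(p, cfg, plan, X_l, "l")
  cb_r <- conv_branch_fwd(p, cfg, plan, X_r, "r")
  X0 <- matrix(0, B * T2, cfg$mlp_hidden)
  X0[plan$xl_rows, ] <- cb_l$M
  X0[plan$xr_rows, ] <- cb_r$M

  layer_caches <- vector("list", cfg$n_encoder_layers)
  attn_maps <- if (keep_attention) vector("list", cfg$n_encoder_layers)
  Xin <- X0
  for (l in seq_len(cfg$n_encoder_layers)) {
    pre <- paste0("enc", l, "_")
    Q <- add_bias(Xin %*% p[[paste0(pre, "wq")]], p[[paste0(pre, "bq")]])
    K <- add_bias(Xin %*% p[[paste0(pre, "wk")]], p[[paste0(pre, "bk")]])
    V <- add_bias(Xin %*% p[[paste0(pre, "wv")]], p[[paste0(pre, "bv")]])
    rel <- p[[paste0(pre, "rel")]]
    relmats <- lapply(seq_len(H), function(h) {
      matrix(rel[h, ][plan$didx_vec], T2, T2)
    })
    O <- matrix(0, B * T2, cfg$d_value_total)
    A_list <- vector("list", B * H)
    if (keep_attention) attn_maps[[l]] <- array(0, c(H, T2, T2))
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T2 + seq_len(T2)
      for (h in seq_len(H)) {
        qc <- (h - 1L) * dk + seq_len(dk)
        vc <- (h - 1L) * dv + seq_len(dv)
        S <- tcrossprod(Q[rb, qc, drop = FALSE], K[rb, qc, drop = FALSE]) /
          sqrt(dk) + relmats[[h]]
        S <- S - S[cbind(seq_len(T2), max.col(S, ties.method = "first"))]
        A <- exp(S)
        A <- A / rowSums(A)
        A_list[[(b - 1L) * H + h]] <- A
        O[rb, vc] <- A %*% V[rb, vc, drop = FALSE]
        if (keep_attention && b == 1L) attn_maps[[l]][h, , ] <- A
      }
    }
    AO <- add_bias(O %*% p[[paste0(pre, "wo")]], p[[paste0(pre, "bo")]])
    m1 <- dropout_mask(nrow(AO), ncol(AO), cfg$dropout, train)
    R1 <- Xin + apply_mask(AO, m1)
    ln1 <- layernorm_fwd(R1, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    F1pre <- add_bias(ln1$y %*% p[[paste0(pre, "ff_w1")]], p[[paste0(pre, "ff_b1")]])
    fmask <- F1pre > 0
    F1 <- F1pre * fmask
    F2 <- add_bias(F1 %*% p[[paste0(pre, "ff_w2")]], p[[paste0(pre, "ff_b2")]])
    m2 <- dropout_mask(nrow(F2), ncol(F2), cfg$dropout, train)
    R2 <- ln1$y + apply_mask(F2, m2)
    ln2 <- layernorm_fwd(R2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    layer_caches[[l]] <- list(
      Xin = Xin, Q = Q, K = K, V = V, A_list = A_list, O = O,
      m1 = m1, ln1 = ln1, X1 = ln1$y, F1 = F1, fmask = fmask,
      m2 = m2, ln2 = ln2
    )
    Xin <- ln2$y
  }
  X2 <- Xin

  pl <- rowsum(X2[plan$xl_rows, , drop = FALSE], plan$grp_pool) / plan$Tm
  pr <- rowsum(X2[plan$xr_rows, , drop = FALSE], plan$grp_pool) / plan$Tm
  Hl_pre <- add_bias(pl %*% p$head_l_w, p$head_l_b)
  hl_mask <- Hl_pre > 0
  Hl <- Hl_pre * hl_mask
  zl <- drop(Hl %*% p$head_l_v) + p$head_l_c
  Hr_pre <- add_bias(pr %*% p$head_r_w, p$head_r_b)
  hr_mask <- Hr_pre > 0
  Hr <- Hr_pre * hr_mask
  zr <- drop(Hr %*% p$head_r_v) + p$head_r_c
  logit <- unname((zl + zr) / 2)
  prob <- 1 / (1 + exp(-logit))

  list(
    prob = prob, logit = logit,
    cache = list(
      cb_l = cb_l, cb_r = cb_r, layer_caches = layer_caches, X2 = X2,
      pl = pl, pr = pr, Hl = Hl, hl_mask = hl_mask,
      Hr = Hr, hr_mask = hr_mask
    ),
    attention = attn_maps
  )
}

# backward pass; returns parameter gradients and input gradients
etnet_backward_core <- function(model, fwd, plan, dlogit, want_input_grad = FALSE) {
  cfg <- model$config
  p <- model$params
  ca <- fwd$cache
  H <- cfg$n_heads
  dk <- cfg$d_qk_total %/% H
  dv <- cfg$d_value_total %/% H
  T2 <- plan$T2
  B <- plan$B
  g <- list()

  dz <- dlogit / 2
  g$head_l_v <- crossprod(ca$Hl, dz)
  g$head_l_c <- sum(dz)
  dHl <- outer(dz, drop(p$head_l_v)) * ca$hl_mask
  g$head_l_w <- crossprod(ca$pl, dHl)
  g$head_l_b <- colSums(dHl)
  dpl <- dHl %*% t(p$head_l_w)
  g$head_r_v <- crossprod(ca$Hr, dz)
  g$head_r_c <- sum(dz)
  dHr <- outer(dz, drop(p$head_r_v)) * ca$hr_mask
  g$head_r_w <- crossprod(ca$pr, dHr)
  g$head_r_b <- colSums(dHr)
  dpr <- dHr %*% t(p$head_r_w)

  dX <- matrix(0, B * T2, cfg$mlp_hidden)
  dX[plan$xl_rows, ] <- dpl[plan$grp_pool, , drop = FALSE] / plan$Tm
  dX[plan$xr_rows, ] <- dpr[plan$grp_pool, , drop = FALSE] / plan$Tm

  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    pre <- paste0("enc", l, "_")
    lc <- ca$layer_caches[[l]]
    ln2b <- layernorm_bwd(dX, lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- ln2b$dg
    g[[paste0(pre, "ln2_b")]] <- ln2b$db
    dR2 <- ln2b$dx
    dF2 <- apply_mask(dR2, lc$m2)
    g[[paste0(pre, "ff_w2")]] <- crossprod(lc$F1, dF2)
    g[[paste0(pre, "ff_b2")]] <- colSums(dF2)
    dF1 <- (dF2 %*% t(p[[paste0(pre, "ff_w2")]])) * lc$fmask
    g[[paste0(pre, "ff_w1")]] <- crossprod(lc$X1, dF1)
    g[[paste0(pre, "ff_b1")]] <- colSums(dF1)
    dX1 <- dR2 + dF1 %*% t(p[[paste0(pre, "ff_w1")]])
    ln1b <- layernorm_bwd(dX1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- ln1b$dg
    g[[paste0(pre, "ln1_b")]] <- ln1b$db
    dR1 <- ln1b$dx
    dAO <- apply_mask(dR1, lc$m1)
    g[[paste0(pre, "wo")]] <- crossprod(lc$O, dAO)
    g[[paste0(pre, "bo")]] <- colSums(dAO)
    dO <- dAO %*% t(p[[paste0(pre, "wo")]])
    dQ <- matrix(0, B * T2, cfg$d_qk_total)
    dK <- matrix(0, B * T2, cfg$d_qk_total)
    dV <- matrix(0, B * T2, cfg$d_value_total)
    dSsum <- lapply(seq_len(H), function(h) matrix(0, T2, T2))
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T2 + seq_len(T2)
      for (h in seq_len(H)) {
        qc <- (h - 1L) * dk + seq_len(dk)
        vc <- (h - 1L) * dv + seq_len(dv)
        A <- lc$A_list[[(b - 1L) * H + h]]
        dOh <- dO[rb, vc, drop = FALSE]
        dA <- tcrossprod(dOh, lc$V[rb, vc, drop = FALSE])
        dV[rb, vc] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dSsum[[h]] <- dSsum[[h]] + dS
        dQ[rb, qc] <- dS %*% lc$K[rb, qc, drop = FALSE] / sqrt(dk)
        dK[rb, qc] <- crossprod(dS, lc$Q[rb, qc, drop = FALSE]) / sqrt(dk)
      }
    }
    drel <- matrix(0, H, 2L * T2 - 1L)
    for (h in seq_len(H)) {
      drel[h, ] <- rowsum(as.vector(dSsum[[h]]), plan$didx_vec)[, 1]
    }
    g[[paste0(pre, "rel")]] <- drel
    g[[paste0(pre, "wq")]] <- crossprod(lc$Xin, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "wk")]] <- crossprod(lc$Xin, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "wv")]] <- crossprod(lc$Xin, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dX <- dR1 + dQ %*% t(p[[paste0(pre, "wq")]]) +
      dK %*% t(p[[paste0(pre, "wk")]]) +
      dV %*% t(p[[paste0(pre, "wv")]])
  }

  dMl <- dX[plan$xl_rows, , drop = FALSE]
  dMr <- dX[plan$xr_rows, , drop = FALSE]
  bl <- conv_branch_bwd(p, cfg, plan, ca$cb_l, dMl, "l", want_input_grad)
  br <- conv_branch_bwd(p, cfg, plan, ca$cb_r, dMr, "r", want_input_grad)
  g$mlp_w <- bl$dWm + br$dWm
  g$mlp_b <- bl$dbm + br$dbm
  if (cfg$tie_conv) {
    g$conv_w <- bl$dWc + br$dWc
    g$conv_b <- bl$dbc + br$dbc
  } else {
    g$conv_w <- bl$dWc
    g$conv_b <- bl$dbc
    g$conv_w_r <- br$dWc
    g$conv_b_r <- br$dbc
  }
  out <- list(grads = g)
  if (want_input_grad) {
    out$dX_l <- bl$dX
    out$dX_r <- br$dX
  }
  out
}

# engine selection: the compiled core is the default; the pure-R reference
# implementation remains available via options(etnet.engine = "r")
use_cpp_engine <- function() {
  !identical(getOption("etnet.engine", "cpp"), "r")
}

cpp_dims <- function(cfg, B) {
  list(
    B = as.integer(B), L = cfg$seq_len, k = cfg$conv_kernel,
    P = cfg$pool_factor, C = cfg$conv_channels, D = cfg$mlp_hidden,
    H = cfg$n_heads, dqk = cfg$d_qk_total, dv = cfg$d_value_total,
    ffn = cfg$ffn_dim, layers = cfg$n_encoder_layers, tie_conv = cfg$tie_conv
  )
}

stack_inputs <- function(x, seq_len) {
  if (is.matrix(x)) x <- list(x)
  for (m in x) {
    if (!is.matrix(m) || ncol(m) != 4L || nrow(m) != seq_len) {
      abort(paste0(
        "input matrices must be ", seq_len, " x 4 one-hot matrices"
      ))
    }
  }
  list(X = do.call(rbind, x), B = length(x))
}

#' Forward pass: interaction probability for one-hot sequence pairs
#'
#' @param model An `etnet_model`.
#' @param left,right A single `seq_len x 4` one-hot matrix, or a list of such
#'   matrices (a batch; both sides must have equal batch size).
#' @return Numeric vector of probabilities in (0, 1), one per pair.
#' @export
etnet_forward <- function(model, left, right) {
  cfg <- model$config
  sl <- stack_inputs(left, cfg$seq_len)
  sr <- stack_inputs(right, cfg$seq_len)
  if (sl$B != sr$B) abort("left and right batches differ in size")
  if (use_cpp_engine()) {
    res <- cpp_batch(model$params, cpp_dims(cfg, sl$B), sl$X, sr$X,
      NULL, 0, FALSE, FALSE, FALSE
    )
    return(res$prob)
  }
  plan <- make_plan(cfg, sl$B)
  etnet_forward_core(model, sl$X, sr$X, plan)$prob
}

#' @export
predict.etnet_model <- function(object, left, right, ...) {
  etnet_forward(object, left, right)
}

#' Per-head attention matrices for one sequence pair
#'
#' Runs the encoder on a single pair and returns, for every layer, the
#' row-stochastic attention matrix of each head over the concatenated
#' left+right token axis.
#'
#' @param model An `etnet_model`.
#' @param left,right `seq_len x 4` one-hot matrices.
#' @return A list with one `(n_heads, tokens, tokens)` array per encoder
#'   layer.
#' @export
attention_maps <- function(model, left, right) {
  cfg <- model$config
  sl <- stack_inputs(left, cfg$seq_len)
  sr <- stack_inputs(right, cfg$seq_len)
  if (sl$B != 1L || sr$B != 1L) abort("attention_maps expects a single pair")
  plan <- make_plan(cfg, 1L)
  etnet_forward_core(model, sl$X, sr$X, plan, keep_attention = TRUE)$attention
}

#' Gradient of the output logit with respect to the input one-hot matrices
#'
#' Used by attribution: returns `d logit / d input` for each side of a single
#' pair, evaluated at the supplied (possibly non-binary) input matrices.
#'
#' @param model An `etnet_model`.
#' @param left,right `seq_len x 4` input matrices.
#' @return List with `left` and `right` gradient matrices of the same shape.
#' @export
input_gradient <- function(model, left, right) {
  cfg <- model$config
  stopifnot(is.matrix(left), is.matrix(right))
  if (use_cpp_engine()) {
    res <- cpp_batch(model$params, cpp_dims(cfg, 1L), left, right,
      NULL, 0, FALSE, FALSE, TRUE
    )
    return(list(left = res$dX_l, right = res$dX_r, prob = res$prob))
  }
  plan <- make_plan(cfg, 1L)
  fwd <- etnet_forward_core(model, left, right, plan)
  bwd <- etnet_backward_core(model, fwd, plan, dlogit = 1, want_input_grad = TRUE)
  list(left = bwd$dX_l, right = bwd$dX_r, prob = fwd$prob)
}

#' A predict-contract scorer closure from a trained model
#'
#' Wraps a model into a `function(left_seq, right_seq) -> probability` over
#' DNA strings of length `seq_len`, the common interface shared with
#' surrogate scorers (see [make_surrogate_scorer()]) used by the
#' perturbation tools.
#'
#' @param model An `etnet_model`.
#' @return A scorer function taking two DNA strings (each of length
#'   `seq_len`, vectorized over equal-length character vectors) and returning
#'   probabilities.
#' @export
etnet_scorer <- function(model) {
  cfg <- model$config
  function(left_seq, right_seq) {
    stopifnot(length(left_seq) == length(right_seq))
    lv <- lapply(left_seq, one_hot_encode)
    rv <- lapply(right_seq, one_hot_encode)
    etnet_forward(model, lv, rv)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.etnet_model <- function(x, ...) {
  tibble(
    parameter = names(x$params),
    group = unname(x$groups[names(x$params)]),
    n_values = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' @export
glance.etnet_model <- function(x, ...) {
  cfg <- x$config
  tibble(
    seq_len = cfg$seq_len, conv_channels = cfg$conv_channels,
    conv_kernel = cfg$conv_kernel, tokens = n_tokens(cfg),
    n_heads = cfg$n_heads, n_encoder_layers = cfg$n_encoder_layers,
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full configuration alongside the parameters, so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model An `etnet_model`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint` the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "etnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "etnet_model")) abort("not an etnet checkpoint")
  m
}
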