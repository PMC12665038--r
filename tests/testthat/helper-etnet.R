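# shared fixtures and memoized expensive objects (trained models are reused
# across test blocks; first access pays the training cost)
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# desk-scale model configuration used throughout the tests
reduced_config <- function(dropout = 0.1, ...) {
  etnet_config(
    seq_len = 200L, conv_channels = 16L, conv_kernel = 9L,
    pool_factor = 8L, mlp_hidden = 32L, n_heads = 2L,
    d_value_total = 32L, d_qk_total = 32L, n_encoder_layers = 1L,
    ffn_dim = 64L, dropout = dropout, head_hidden = 16L, ...
  )
}

# minimal configuration for gradient checks and engine comparisons
tiny_config <- function(...) {
  etnet_config(
    seq_len = 16L, conv_channels = 6L, conv_kernel = 5L,
    pool_factor = 4L, mlp_hidden = 6L, n_heads = 2L,
    d_value_total = 4L, d_qk_total = 4L, n_encoder_layers = 2L,
    ffn_dim = 8L, dropout = 0, head_hidden = 3L, ...
  )
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_onehot <- function(L) one_hot_encode(random_dna(L))

test_fixture <- function() {
  memo("fixture", make_fixture(fixture_spec(seed = 101L)))
}

test_manifest <- function() {
  memo("manifest", fixture_dataset(test_fixture(), seed = 101L))
}

# training protocol used for the desk-scale generalization experiments:
# 1,500 balanced training pairs, Adam lr 3e-3, weight decay 2e-3, dropout
# 0.1, 150 epochs, best-validation-AUC checkpoint
trained_fixture_fit <- function() {
  memo("trained_fit", {
    fx <- test_fixture()
    man <- test_manifest()
    tr <- which(man$split == "train")
    withr::with_seed(2, {
      p <- tr[man$label[tr] == "positive"]
      q <- tr[man$label[tr] == "negative"]
      keep <- sort(c(sample(p, 750), sample(q, 750)))
    })
    man2 <- man
    man2$split[setdiff(tr, keep)] <- "unused"
    model <- build_model(reduced_config(), seed = 5)
    etnet_train(model, man2, fx$genome,
      lr = 3e-3, epochs = 150, batch_size = 50, seed = 5,
      weight_decay = 2e-3, restarts = 3
    )
  })
}

# dinucleotide count table of a sequence (named by 2-mer)
dinuc_counts <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 2) return(table(character()))
  table(paste0(chars[-length(chars)], chars[-1]))
}

expect_same_dinucs <- function(a, b) {
  ta <- dinuc_counts(a)
  tb <- dinuc_counts(b)
  expect_identical(sort(names(ta)), sort(names(tb)))
  expect_identical(as.integer(ta[sort(names(ta))]), as.integer(tb[sort(names(tb))]))
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
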