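# small in-memory genome + manifest for fast training tests: 40 pairs whose
# label is fully determined by a planted motif pair
tiny_train_setup <- function() {
  memo("tiny_train", {
    withr::with_seed(21, {
      n <- 40L
      L <- 16L
      motif_a <- "TTGACG"
      motif_b <- "CCATGG"
      lab <- rep(c(1L, 0L), n / 2)
      mk_seq <- function(has) {
        s <- random_dna(L)
        if (has == 1L) {
          substr(s, 4, 9) <- motif_a
        }
        s
      }
      left <- vapply(lab, mk_seq, character(1))
      right <- vapply(lab, function(h) {
        s <- random_dna(L)
        if (h == 1L) substr(s, 6, 11) <- motif_b
        s
      }, character(1))
      chrom_seq <- paste0(left, right, collapse = "")
      genome <- structure(
        list(chr1 = chrom_seq),
        sizes = c(chr1 = nchar(chrom_seq)), class = "eei_genome"
      )
      offs <- (seq_len(n) - 1L) * 2L * L
      man <- tibble::tibble(
        left_chrom = "chr1", left_start = offs, left_end = offs + L,
        left_id = paste0("EL", seq_len(n)),
        right_chrom = "chr1", right_start = offs + L, right_end = offs + 2L * L,
        right_id = paste0("ER", seq_len(n)),
        label = ifelse(lab == 1L, "positive", "negative"),
        loop_id = NA_character_, distance = NA_real_,
        se_category = "unassigned",
        split = c(rep("train", 30L), rep("validation", 10L))
      )
      list(genome = genome, manifest = man)
    })
  })
}

tiny_model <- function(seed = 1) {
  build_model(tiny_config(), seed = seed)
}

test_that("training reduces the loss and retains the best-validation model", {
  st <- tiny_train_setup()
  fit <- etnet_train(tiny_model(), st$manifest, st$genome,
    lr = 3e-3, epochs = 12, batch_size = 10, seed = 1
  )
  h <- fit$history
  expect_identical(nrow(h), 12L)
  expect_lt(mean(h$loss[9:12]), mean(h$loss[1:4]))
  expect_true(all(c("epoch", "loss", "val_auc") %in% names(h)))
  expect_identical(fit$val_auc, max(h$val_auc))
  expect_s3_class(glance(fit), "tbl_df")
  expect_error(
    etnet_train(tiny_model(), dplyr::mutate(st$manifest, split = "test"),
      st$genome
    ),
    "empty training split"
  )
})

test_that("training is reproducible from the seed", {
  st <- tiny_train_setup()
  f1 <- etnet_train(tiny_model(), st$manifest, st$genome,
    lr = 3e-3, epochs = 4, batch_size = 10, seed = 7
  )
  f2 <- etnet_train(tiny_model(), st$manifest, st$genome,
    lr = 3e-3, epochs = 4, batch_size = 10, seed = 7
  )
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts after patience epochs without improvement", {
  st <- tiny_train_setup()
  fit <- etnet_train(tiny_model(), st$manifest, st$genome,
    lr = 0, epochs = 40, batch_size = 10, seed = 2, patience = 3
  )
  # constant model: no improvement after epoch 1, stop at 1 + patience
  expect_identical(nrow(fit$history), 4L)
})

test_that("selective fine-tuning freezes every encoder parameter bitwise", {
  st <- tiny_train_setup()
  base <- etnet_train(tiny_model(), st$manifest, st$genome,
    lr = 3e-3, epochs = 3, batch_size = 10, seed = 3
  )$model
  ft <- finetune_selective(base, st$manifest, st$genome,
    lr = 1e-3, epochs = 3, patience = 5, batch_size = 10, seed = 4
  )$model
  enc <- names(base$groups)[base$groups == "encoder"]
  for (nm in enc) {
    expect_identical(ft$params[[nm]], base$params[[nm]])
  }
  expect_false(identical(ft$params$conv_w, base$params$conv_w))
  expect_false(identical(ft$params$mlp_w, base$params$mlp_w))
  expect_false(identical(ft$params$head_l_w, base$params$head_l_w))
  broken <- base
  broken$groups <- broken$groups[broken$groups != "encoder"]
  expect_error(
    finetune_selective(broken, st$manifest, st$genome),
    "encoder"
  )
})

test_that("confusion counts and derived metrics match the printed formulas", {
  # TP=3, TN=4, FP=1, FN=2
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  scores <- c(.9, .8, .7, .2, .1, .6, .4, .3, .2, .1)
  cc <- eei_confusion(labels, scores)
  expect_identical(as.integer(cc), c(3L, 4L, 1L, 2L))
  m <- eei_metrics(labels, scores)$metrics
  expect_equal(m$ACC, 0.7)
  expect_equal(m$Precision, 0.75)
  expect_equal(m$Recall, 0.6)
  expect_equal(m$F1, 2 * (0.75 * 0.6) / (0.75 + 0.6))
})

test_that("AUC follows the trapezoidal/Mann-Whitney convention with ties at 1/2", {
  expect_equal(
    eei_metrics(c(1, 1, 0, 0), c(.9, .8, .7, .1))$metrics$AUC, 1
  )
  expect_equal(
    eei_metrics(c(1, 0), c(.6, .6))$metrics$AUC, 0.5
  )
  expect_error(eei_metrics(c(1, 1), c(.2, .3)), "single-class")
  # agreement with an independent rank-based implementation on random vectors
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(10:60, 1)
      lab <- rbinom(n, 1, 0.5)
      if (length(unique(lab)) < 2) next
      sc <- round(runif(n), sample(1:3, 1)) # force ties
      m <- eei_metrics(lab, sc)$metrics
      r <- rank(sc)
      n1 <- sum(lab == 1)
      auc_rank <- (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * sum(lab == 0))
      expect_equal(m$AUC, auc_rank, tolerance = 1e-10)
    }
  })
})

test_that("AUC and AUPR agree with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    for (i in 1:25) {
      n <- 50
      lab <- rbinom(n, 1, 0.5)
      if (length(unique(lab)) < 2) next
      sc <- runif(n)
      m <- eei_metrics(lab, sc)$metrics
      expect_equal(
        m$AUC,
        as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<"))),
        tolerance = 1e-10
      )
    }
  })
})

# exhaustive DeLong oracle: U-statistic components from first principles
delong_oracle <- function(labels, sa, sb) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  kern <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(s) {
    v10 <- vapply(pos, function(i) mean(kern(s[i], s[neg])), numeric(1))
    v01 <- vapply(neg, function(j) mean(kern(s[pos], s[j])), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- comp(sa)
  b <- comp(sb)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_d <- s10[1, 1] / length(pos) + s10[2, 2] / length(pos) -
    2 * s10[1, 2] / length(pos) +
    s01[1, 1] / length(neg) + s01[2, 2] / length(neg) -
    2 * s01[1, 2] / length(neg)
  list(delta = a$auc - b$auc, var = var_d)
}

test_that("paired DeLong variance equals exhaustive U-statistic enumeration", {
  labels <- c(1, 1, 1, 0, 0, 0)
  sa <- c(.9, .6, .4, .5, .3, .1)
  sb <- c(.8, .7, .2, .6, .4, .2)
  r <- delong_paired(labels, sa, sb)
  o <- delong_oracle(labels, sa, sb)
  expect_equal(r$delta_auc, o$delta, tolerance = 1e-12)
  expect_equal(r$var_delta, o$var, tolerance = 1e-12)
  withr::with_seed(33, {
    for (i in 1:25) {
      n <- sample(8:20, 1)
      lab <- c(rep(1, 4), rbinom(n - 8, 1, .5), rep(0, 4))
      sa <- round(runif(n), 2)
      sb <- round(runif(n), 2)
      r <- delong_paired(lab, sa, sb)
      o <- delong_oracle(lab, sa, sb)
      expect_equal(r$var_delta, o$var, tolerance = 1e-12)
      expect_equal(r$delta_auc, o$delta, tolerance = 1e-12)
    }
  })
})

test_that("DeLong edge cases: identical scores, degenerate variance, consistency", {
  labels <- c(1, 1, 0, 0, 1, 0)
  s <- c(.9, .8, .3, .2, .7, .1)
  r <- delong_paired(labels, s, s)
  expect_identical(r$delta_auc, 0)
  expect_identical(r$p_value, 1)
  # DeLong AUC equals the metrics AUC on the same scores
  expect_equal(r$auc_a, eei_metrics(labels, s)$metrics$AUC, tolerance = 1e-12)
  # perfectly separated scores on both sides: zero variance, unequal AUCs
  expect_warning(
    r2 <- delong_paired(c(1, 1, 0, 0), c(.9, .8, .1, .2), c(.1, .2, .8, .9)),
    "degenerate"
  )
  expect_lt(r2$p_value, 1e-200)
  expect_error(delong_paired(c(1, 1), c(.1, .2), c(.3, .4)), "single-class")
})

test_that("per-category evaluation partitions the test set and flags tiny groups", {
  withr::with_seed(34, {
    scored <- tibble::tibble(
      label = rep(c("positive", "negative"), 40),
      score = runif(80),
      se_category = rep(c("SE_intra", "SE_out"), each = 40)
    )
  })
  out <- evaluate_by_category(scored, "se_category", min_size = 20)
  expect_identical(out$group, c("SE_intra", "SE_out", "overall"))
  expect_identical(out$n, c(40L, 40L, 80L))
  expect_false(any(out$flagged))
  # one single-class group -> flagged with metrics omitted
  scored2 <- scored
  scored2$label[scored2$se_category == "SE_intra"] <- "positive"
  out2 <- evaluate_by_category(scored2, "se_category")
  expect_true(out2$flagged[out2$group == "SE_intra"])
  expect_true(is.na(out2$AUC[out2$group == "SE_intra"]))
  expect_error(evaluate_by_category(scored, "nope"), "unknown group_key")
})

test_that("manifest scoring appends calibrated probabilities per split", {
  st <- tiny_train_setup()
  model <- tiny_model()
  sc <- predict_manifest(model, st$manifest, st$genome, split = "validation")
  expect_identical(nrow(sc), sum(st$manifest$split == "validation"))
  expect_true(all(sc$score > 0 & sc$score < 1))
})
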