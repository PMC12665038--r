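test_that("dinucleotide shuffling conserves counts and fixed points", {
  expect_identical(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  # ATATAT admits a single sequence with its dinucleotide counts: verify by
  # enumerating every length-6 AT-string as an independent oracle
  counts_of <- function(s) {
    t <- dinuc_counts(s)
    paste(sort(paste0(names(t), t)), collapse = ",")
  }
  target <- counts_of("ATATAT")
  grid <- expand.grid(rep(list(c("A", "T")), 6), stringsAsFactors = FALSE)
  all6 <- apply(grid, 1, paste, collapse = "")
  expect_identical(all6[vapply(all6, counts_of, character(1)) == target], "ATATAT")
  for (s in 1:5) {
    expect_identical(dinucleotide_shuffle("ATATAT", seed = s), "ATATAT")
  }
})

test_that("dinucleotide conservation holds for random sequences of all lengths", {
  withr::with_seed(51, {
    for (i in 1:150) {
      s <- random_dna(sample(2:500, 1))
      sh <- dinucleotide_shuffle(s)
      expect_identical(nchar(sh), nchar(s))
      expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
      expect_identical(
        substr(sh, nchar(sh), nchar(sh)),
        substr(s, nchar(s), nchar(s))
      )
      expect_same_dinucs(s, sh)
    }
  })
})

test_that("N positions are held fixed and runs shuffle independently", {
  s <- "ACGTACGTNNACGTACGTAC"
  withr::with_seed(52, {
    for (i in 1:20) {
      sh <- dinucleotide_shuffle(s)
      expect_identical(substr(sh, 9, 10), "NN")
      expect_same_dinucs(substr(s, 1, 8), substr(sh, 1, 8))
      expect_same_dinucs(substr(s, 11, 20), substr(sh, 11, 20))
    }
  })
  # same seed -> same shuffle
  long <- random_dna(300)
  expect_identical(
    dinucleotide_shuffle(long, seed = 3),
    dinucleotide_shuffle(long, seed = 3)
  )
})

test_that("shuffles are non-trivial for complex sequences", {
  withr::with_seed(53, {
    s <- random_dna(200)
    shuffles <- vapply(1:10, function(i) dinucleotide_shuffle(s), character(1))
  })
  expect_gt(length(unique(shuffles)), 5)
  expect_false(any(shuffles == s))
})

make_additive_setup <- function(weights_left, weights_right, region_size = 20L) {
  nl <- length(weights_left) * region_size
  nr <- length(weights_right) * region_size
  withr::with_seed(54, {
    left <- random_dna(nl)
    right <- random_dna(nr)
  })
  scorer <- make_surrogate_scorer("additive",
    left_ref = left, right_ref = right, region_size = region_size,
    weights_left = weights_left, weights_right = weights_right
  )
  list(left = left, right = right, scorer = scorer)
}

test_that("greedy search on an additive surrogate equals exhaustive ordering", {
  # weights distinct: greedy must select regions in descending weight order,
  # which for an additive scorer is the exhaustive optimum
  su <- make_additive_setup(c(3, 1, 5), c(2, 4, 6))
  g <- greedy_region_search(su$scorer, su$left, su$right,
    region_size = 20L, n_shuffles = 2, seed = 1
  )
  sel <- selected_regions(g)
  expect_identical(nrow(sel), 6L)
  wmap <- c(3, 1, 5, 2, 4, 6)
  picked <- ifelse(sel$side == "left", sel$region, sel$region + 3L)
  expect_identical(wmap[picked], sort(wmap, decreasing = TRUE))
  # selected regions are pairwise disjoint per side
  for (sd in c("left", "right")) {
    ss <- sel[sel$side == sd, ]
    expect_false(any(duplicated(ss$start)))
  }
  # randomized repeat with fresh weights
  withr::with_seed(55, {
    for (i in 1:5) {
      wl <- sample(seq(1, 40), 3)
      wr <- sample(seq(41, 80), 3)
      su <- make_additive_setup(wl, wr)
      sel <- selected_regions(greedy_region_search(su$scorer, su$left, su$right,
        region_size = 20L, n_shuffles = 1, seed = i
      ))
      w <- c(wl, wr)
      picked <- ifelse(sel$side == "left", sel$region, sel$region + 3L)
      expect_identical(w[picked], sort(w, decreasing = TRUE))
    }
  })
})

test_that("constant scorers give zero deltas with leftmost tie-breaking", {
  scorer <- make_surrogate_scorer("constant", value = 0.4)
  withr::with_seed(56, {
    l <- random_dna(60)
    r <- random_dna(60)
  })
  g <- greedy_region_search(scorer, l, r,
    region_size = 20L, n_shuffles = 2,
    max_iters = 2, seed = 1
  )
  expect_true(all(unlist(g$deltas) == 0))
  sel <- selected_regions(g)
  # ties broken left side first, leftmost region first
  expect_identical(sel$side, c("left", "left"))
  expect_identical(sel$start, c(0L, 20L))
  expect_warning(
    greedy_region_search(scorer, l, r,
      region_size = 20L, n_shuffles = 1,
      max_iters = 99, seed = 1
    ),
    "clipped"
  )
})

test_that("synergy is zero for additive scorers and positive for joint-only gates", {
  su <- make_additive_setup(c(2, 3, 4), c(5, 6, 7))
  s_add <- synergy(su$scorer, su$left, su$right,
    region_left = c(0L, 20L), region_right = c(20L, 40L),
    n_shuffles = 5, seed = 2
  )
  # paired replicates make additivity exact, not just within Monte-Carlo error
  expect_equal(s_add$synergy, 0, tolerance = 1e-12)
  expect_identical(s_add$classification, "additive-or-sub-additive")
  # prediction drops only when both designated regions are hit jointly
  withr::with_seed(57, {
    l <- random_dna(60)
    r <- random_dna(60)
  })
  gate <- make_surrogate_scorer("and_gate",
    left_ref = l, right_ref = r,
    left_region = c(0L, 20L), right_region = c(40L, 60L)
  )
  s_gate <- synergy(gate, l, r,
    region_left = c(0L, 20L), region_right = c(40L, 60L),
    n_shuffles = 5, seed = 3
  )
  expect_equal(s_gate$delta_left, 0)
  expect_equal(s_gate$delta_right, 0)
  expect_equal(s_gate$delta_joint, 0.98)
  expect_equal(s_gate$synergy, 0.98)
  expect_identical(s_gate$classification, "super-additive")
  # internal consistency
  expect_equal(
    s_gate$synergy,
    s_gate$delta_joint - s_gate$delta_left - s_gate$delta_right
  )
})

test_that("synergy surveys recover population composition and correlations", {
  withr::with_seed(58, {
    pairs_add <- tibble::tibble(
      left_seq = replicate(4, random_dna(60)),
      right_seq = replicate(4, random_dna(60))
    )
  })
  # a scorer that is exactly additive across sides for any input pair:
  # score depends on the sum of per-side 3-mer counts (which dinucleotide
  # shuffling perturbs), so joint deltas equal the sum of individual deltas
  acg_count <- function(s) {
    lengths(regmatches(s, gregexpr("ACG", s, fixed = TRUE)))
  }
  additive_global <- function(l, r) {
    pmin(0.95, 0.05 + 0.05 * (acg_count(l) + acg_count(r)))
  }
  # synergy is exactly constant (zero) here, so the correlation is undefined
  expect_warning(
    sv <- synergy_survey(additive_global, pairs_add,
      region_size = 20L, n_shuffles = 3, seed = 4, tau = 1e-9
    ),
    "undefined"
  )
  expect_equal(sv$fraction_super, 0)
  # population of joint-only gates: every pair is super-additive
  withr::with_seed(59, {
    pairs_gate <- tibble::tibble(
      left_seq = replicate(4, random_dna(60)),
      right_seq = replicate(4, random_dna(60))
    )
  })
  gate_all <- function(l, r) {
    vapply(seq_along(l), function(k) {
      i <- which.max(vapply(seq_len(4), function(j) {
        (substr(pairs_gate$left_seq[j], 1, 20) == substr(l[k], 1, 20)) +
          (substr(pairs_gate$right_seq[j], 1, 20) == substr(r[k], 1, 20))
      }, numeric(1)))
      gl <- substr(l[k], 1, 20) == substr(pairs_gate$left_seq[i], 1, 20)
      gr <- substr(r[k], 1, 20) == substr(pairs_gate$right_seq[i], 1, 20)
      ifelse(gl | gr, 0.99, 0.01)
    }, numeric(1))
  }
  expect_warning(
    sv2 <- synergy_survey(gate_all, pairs_gate,
      region_size = 20L,
      n_shuffles = 3, seed = 5, region_mode = "whole"
    ),
    "undefined" # every pair has the same synergy (the gate height)
  )
  expect_equal(sv2$fraction_super, 1)
  gl <- glance(sv2)
  expect_identical(gl$n_pairs, 4L)
})

test_that("survey correlations match the direct Pearson formula", {
  # hand-built 5-point check through the public helper
  s <- c(0.5, 0.1, -0.2, 0.4, 0.0)
  sim <- c(0.1, 0.6, 0.9, 0.2, 0.5)
  ct <- stats::cor.test(s, sim)
  expect_equal(unname(ct$estimate), sum(scale(s) * scale(sim)) / 4, tolerance = 1e-12)
  # constant similarity is flagged
  withr::with_seed(60, {
    pairs <- tibble::tibble(
      left_seq = rep(random_dna(40), 3),
      right_seq = rep(random_dna(40), 3)
    )
  })
  expect_warning(
    sv <- synergy_survey(make_surrogate_scorer("constant"), pairs,
      region_size = 20L, n_shuffles = 2, seed = 1, region_mode = "whole"
    ),
    "undefined"
  )
  expect_true(is.na(sv$correlation))
})

test_that("k-mer cosine similarity behaves as a similarity measure", {
  s <- random_dna(100)
  expect_equal(etnet:::kmer_cosine(s, s), 1)
  expect_lte(etnet:::kmer_cosine(s, random_dna(100)), 1)
  expect_gte(etnet:::kmer_cosine(random_dna(100), random_dna(100)), 0)
})

test_that("attribution of a constant-output model is numerically zero", {
  model <- build_model(tiny_config(), seed = 1)
  for (nm in names(model$params)) model$params[[nm]][] <- 0
  withr::with_seed(61, {
    l <- random_dna(16)
    r <- random_dna(16)
  })
  expect_message(
    at <- etnet_attribute(model, l, r, n_references = 3, seed = 2),
    "untrained"
  )
  expect_identical(dim(at$left), c(16L, 4L))
  expect_lt(max(abs(at$left)), 1e-10)
  expect_lt(max(abs(at$right)), 1e-10)
  expect_false(at$meta$model_trained)
  expect_identical(at$meta$n_references, 3L)
})

test_that("attribution shape, determinism and tidy output", {
  model <- build_model(tiny_config(), seed = 5)
  model$trained <- TRUE
  withr::with_seed(62, {
    l <- random_dna(16)
    r <- random_dna(16)
  })
  a1 <- etnet_attribute(model, l, r, n_references = 4, seed = 9)
  a2 <- etnet_attribute(model, l, r, n_references = 4, seed = 9)
  expect_identical(a1$left, a2$left)
  expect_length(a1$left_importance, 16)
  td <- tidy(a1)
  expect_identical(nrow(td), 32L)
  expect_setequal(unique(td$side), c("left", "right"))
})
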