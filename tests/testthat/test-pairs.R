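enh <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(
    chrom = "chr1", start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    id = paste0("E", m[, 3])
  )
}
loop <- function(s1, e1, s2, e2, id = "L1", chrom = "chr1") {
  tibble::tibble(
    chrom1 = chrom, start1 = as.integer(s1), end1 = as.integer(e1),
    chrom2 = chrom, start2 = as.integer(s2), end2 = as.integer(e2),
    loop_id = id
  )
}

test_that("positive pairing requires full containment in the anchors", {
  enhancers <- enh(100, 500, 1, 5100, 5400, 2, 900, 1100, 3)
  pairs <- find_positive_pairs(loop(0, 1000, 5000, 6000), enhancers)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$left_id, "E1")
  expect_identical(pairs$right_id, "E2")
  expect_identical(pairs$label, "positive")
  expect_identical(pairs$loop_id, "L1")
  expect_identical(pairs$distance, 5250 - 300)
  # E3 straddles the left anchor boundary: never paired
  expect_false("E3" %in% c(pairs$left_id, pairs$right_id))
})

test_that("duplicate loops and duplicated unordered pairs collapse to one record", {
  enhancers <- enh(100, 500, 1, 5100, 5400, 2)
  loops <- dplyr::bind_rows(
    loop(0, 1000, 5000, 6000, "L1"),
    loop(0, 1000, 5000, 6000, "L2"),
    loop(5000, 6000, 0, 1000, "L3") # reversed orientation, same unordered pair
  )
  pairs <- find_positive_pairs(loops, enhancers)
  expect_identical(nrow(pairs), 1L)
  # pairing count is invariant to duplicating loop records
  expect_identical(
    nrow(find_positive_pairs(dplyr::bind_rows(loops, loops), enhancers)), 1L
  )
  # loops without contained enhancers give an empty, well-formed manifest
  empty <- find_positive_pairs(loop(9000, 9100, 9500, 9600), enhancers)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("left_id", "right_id", "label") %in% names(empty)))
})

two_pos <- function() {
  enhancers <- enh(100, 500, 1, 5100, 5400, 2, 200, 600, 3, 5500, 5900, 4)
  loops <- dplyr::bind_rows(
    loop(0, 1000, 5000, 5450, "L1"), # contains E1,E3 left and E2 right
    loop(150, 700, 5450, 6000, "L2") # E3 left (E1 excluded), E4 right
  )
  find_positive_pairs(loops, enhancers)
}

test_that("random negatives exclude the positive set and are reproducible", {
  pos <- tibble::tibble(
    left_chrom = "chr1", left_start = c(0L, 100L), left_end = c(50L, 150L),
    left_id = c("E1", "E3"),
    right_chrom = "chr1", right_start = c(1000L, 1100L),
    right_end = c(1050L, 1150L), right_id = c("E2", "E4"),
    label = "positive", loop_id = c("L1", "L2"),
    distance = 1000, se_category = "unassigned"
  )
  neg <- sample_negatives_random(pos, n = 2, seed = 3)
  keys <- pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(
    paste(pmin(neg$left_id, neg$right_id), pmax(neg$left_id, neg$right_id)),
    c("E1 E4", "E2 E3") # the only two admissible combinations
  )
  expect_identical(neg$label, c("negative", "negative"))
  expect_error(sample_negatives_random(pos, n = 3, seed = 1), "only 2")
  expect_identical(
    sample_negatives_random(pos, n = 2, seed = 9),
    sample_negatives_random(pos, n = 2, seed = 9)
  )
})

test_that("fixed-end negatives keep one side of a positive pair", {
  pos <- two_pos()
  # pools {E1,E3} x {E2,E4} with positives (E1,E2),(E3,E2),(E3,E4):
  # the only admissible fixed-end negative is (E1,E4)
  neg <- sample_negatives_fixed_end(pos, n = 1, seed = 2)
  expect_identical(c(neg$left_id, neg$right_id), c("E1", "E4"))
  expect_error(sample_negatives_fixed_end(pos, n = 2, seed = 2), "pool too small")
  # on a larger random positive set every negative shares exactly one
  # enhancer with some positive and never duplicates a positive
  withr::with_seed(10, {
    ids <- sprintf("E%02d", 1:20)
    left <- sample(ids[1:10], 15, replace = TRUE)
    right <- sample(ids[11:20], 15, replace = TRUE)
    keep <- !duplicated(paste(left, right))
    pos2 <- tibble::tibble(
      left_chrom = "chr1", left_start = 0L, left_end = 100L, left_id = left[keep],
      right_chrom = "chr1", right_start = 200L, right_end = 300L,
      right_id = right[keep], label = "positive", loop_id = "L",
      distance = 200, se_category = "unassigned"
    )
  })
  neg2 <- sample_negatives_fixed_end(pos2, n = 10, seed = 6)
  pk <- function(df) paste(pmin(df$left_id, df$right_id), pmax(df$left_id, df$right_id))
  expect_length(intersect(pk(neg2), pk(pos2)), 0)
  pos_ids <- unique(c(pos2$left_id, pos2$right_id))
  expect_true(all(
    (neg2$left_id %in% pos_ids) | (neg2$right_id %in% pos_ids)
  ))
  expect_identical(
    sample_negatives_fixed_end(pos2, n = 10, seed = 4),
    sample_negatives_fixed_end(pos2, n = 10, seed = 4)
  )
})

test_that("single-bin distance matching keeps negatives inside the positive range", {
  # three positives all at 10 kb; admissible candidates (E3,E2) and (E5,E4)
  # also sit at 10 kb, the out-of-range ones at 30-50 kb must be refused
  mk <- function(mid, id) {
    tibble::tibble(
      chrom = "chr1", start = as.integer(mid - 50), end = as.integer(mid + 50),
      id = id
    )
  }
  lefts <- dplyr::bind_rows(mk(0, "E1"), mk(20000, "E3"), mk(40000, "E5"))
  rights <- dplyr::bind_rows(mk(10000, "E2"), mk(30000, "E4"), mk(50000, "E6"))
  pos <- etnet:::build_pair_manifest(lefts, rights, "positive", c("L1", "L2", "L3"))
  neg <- sample_negatives_distance_matched(pos, n = 2, n_bins = 1, seed = 1)
  expect_identical(nrow(neg), 2L)
  expect_true(all(neg$distance >= min(pos$distance) &
    neg$distance <= max(pos$distance)))
  expect_error(sample_negatives_distance_matched(pos[0, ], n = 2, seed = 1))
})

test_that("8:1:1 stratified split preserves class balance and sizes", {
  pairs <- tibble::tibble(
    left_id = paste0("L", 1:100), right_id = paste0("R", 1:100),
    label = rep(c("positive", "negative"), each = 50)
  )
  sp <- split_ratio(pairs, seed = 11)
  expect_identical(
    as.integer(table(sp$split)[c("train", "validation", "test")]),
    c(80L, 10L, 10L)
  )
  tab <- table(sp$split, sp$label)
  expect_identical(as.integer(tab["train", ]), c(40L, 40L))
  expect_identical(as.integer(tab["validation", ]), c(5L, 5L))
  expect_identical(as.integer(tab["test", ]), c(5L, 5L))
})

test_that("k-fold partition is disjoint, exhaustive and balanced in size", {
  pairs <- tibble::tibble(
    left_id = paste0("L", 1:95), right_id = paste0("R", 1:95), label = "positive"
  )
  sp <- split_kfold(pairs, k = 10, seed = 3)
  sizes <- table(sp$fold)
  expect_identical(length(sizes), 10L)
  expect_true(all(sizes %in% c(9L, 10L)))
  expect_identical(sum(sizes), 95L)
  expect_error(split_kfold(pairs[1:5, ], k = 10), "exceeds")
})

test_that("enhancer-level split enforces both leakage constraints", {
  pairs <- tibble::tibble(
    left_id = c("A", "B", "D"), right_id = c("B", "C", "E"), label = "positive"
  )
  # quota of 1 test pair; whichever is chosen, constraint (i) drops overlaps
  sp <- split_enhancer_level(pairs, test_fraction = 0.34, seed = 1)
  test_ids <- c(sp$left_id[sp$split == "test"], sp$right_id[sp$split == "test"])
  train_ids <- c(sp$left_id[sp$split == "train"], sp$right_id[sp$split == "train"])
  expect_length(intersect(test_ids, train_ids), 0)
  expect_true(all(table(test_ids) == 1L))
  # property over random synthetic pair sets
  withr::with_seed(8, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      ids <- paste0("E", 1:15)
      pp <- tibble::tibble(
        left_id = sample(ids, n, replace = TRUE),
        right_id = sample(ids, n, replace = TRUE), label = "positive"
      )
      pp <- pp[pp$left_id != pp$right_id, ]
      if (nrow(pp) == 0) next
      sp <- suppressWarnings(split_enhancer_level(pp, 0.2, seed = i))
      tid <- c(sp$left_id[sp$split == "test"], sp$right_id[sp$split == "test"])
      trid <- c(sp$left_id[sp$split == "train"], sp$right_id[sp$split == "train"])
      expect_length(intersect(tid, trid), 0)
      if (length(tid)) expect_true(all(table(tid) == 1L))
    }
  })
})

test_that("super-enhancer categories follow shared/different/none membership", {
  pairs <- tibble::tibble(
    left_chrom = "chr1", left_start = c(100L, 100L, 9000L),
    left_end = c(200L, 200L, 9100L), left_id = c("E1", "E1", "E5"),
    right_chrom = "chr1", right_start = c(300L, 2100L, 9500L),
    right_end = c(400L, 2200L, 9600L), right_id = c("E2", "E4", "E6"),
    label = "positive", loop_id = NA, distance = 100, se_category = "unassigned"
  )
  se <- tibble::tibble(
    chrom = "chr1", start = c(0L, 2000L), end = c(1000L, 3000L),
    id = c("SE1", "SE2")
  )
  out <- categorize_super_enhancer(pairs, se)
  expect_identical(out$se_category, c("SE_intra", "SE_inter", "SE_out"))
})

test_that("enhancers overlapping two super-enhancers go to the larger overlap", {
  pairs <- tibble::tibble(
    left_chrom = "chr1", left_start = 90L, left_end = 210L, left_id = "E1",
    right_chrom = "chr1", right_start = 120L, right_end = 180L, right_id = "E2",
    label = "positive", loop_id = NA, distance = 0, se_category = "unassigned"
  )
  se <- tibble::tibble(
    chrom = "chr1", start = c(0L, 150L), end = c(150L, 400L), id = c("SE1", "SE2")
  )
  # left overlaps SE1 by 60 and SE2 by 60 (tie -> leftmost SE1);
  # right overlaps SE1 by 30 and SE2 by 30 (tie -> SE1 as well)
  out <- categorize_super_enhancer(pairs, se)
  expect_identical(out$se_category, "SE_intra")
})

test_that("manifests round-trip through TSV", {
  man <- two_pos()
  f <- tempfile(fileext = ".tsv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_identical(back$left_id, man$left_id)
  expect_identical(back$distance, man$distance)
})
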