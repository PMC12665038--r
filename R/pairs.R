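#' Positive enhancer pairs from loops and enhancer annotations
#'
#' For each chromatin-interaction loop, every enhancer fully contained in the
#' left anchor is paired with every enhancer fully contained in the right
#' anchor ("fully overlapped" is read as containment: enhancer within anchor).
#' Duplicate unordered pairs arising from multiple loops are collapsed to one
#' record; all retained pairs are labelled `positive`.
#'
#' @param loops Tibble from [read_bedpe()].
#' @param enhancers Tibble from [read_bed()] with unique `id`s.
#' @return A pair manifest tibble with columns `left_chrom`, `left_start`,
#'   `left_end`, `left_id`, `right_*`, `label`, `loop_id`, `distance`
#'   (midpoint distance in bp, `NA` across chromosomes), `se_category`.
#' @export
find_positive_pairs <- function(loops, enhancers) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2") %in% names(loops)))
  if (anyDuplicated(enhancers$id)) abort("enhancer ids must be unique")
  if (nrow(loops) == 0L || nrow(enhancers) == 0L) {
    return(empty_pair_manifest())
  }
  contained <- function(anchor_chrom, anchor_start, anchor_end) {
    # enhancers fully within each anchor; returns list of enhancer row indices
    enh <- IRanges::IRanges(enhancers$start + 1L, enhancers$end)
    anc <- IRanges::IRanges(anchor_start + 1L, anchor_end)
    hits <- IRanges::findOverlaps(enh, anc, type = "within")
    ok <- enhancers$chrom[S4Vectors::queryHits(hits)] ==
      anchor_chrom[S4Vectors::subjectHits(hits)]
    split(
      S4Vectors::queryHits(hits)[ok],
      factor(S4Vectors::subjectHits(hits)[ok], levels = seq_along(anchor_chrom))
    )
  }
  left_hits <- contained(loops$chrom1, loops$start1, loops$end1)
  right_hits <- contained(loops$chrom2, loops$start2, loops$end2)
  rows <- purrr::map(seq_len(nrow(loops)), function(i) {
    li <- left_hits[[i]]
    ri <- right_hits[[i]]
    if (length(li) == 0L || length(ri) == 0L) return(NULL)
    grid <- expand.grid(l = li, r = ri)
    grid <- grid[grid$l != grid$r, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    tibble(l = grid$l, r = grid$r, loop_id = loops$loop_id[i])
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0L) return(empty_pair_manifest())
  rows$key <- pair_key(enhancers$id[rows$l], enhancers$id[rows$r])
  rows <- rows[!duplicated(rows$key), , drop = FALSE]
  build_pair_manifest(enhancers[rows$l, ], enhancers[rows$r, ],
    label = "positive", loop_id = rows$loop_id
  )
}

empty_pair_manifest <- function() {
  tibble(
    left_chrom = character(), left_start = integer(), left_end = integer(),
    left_id = character(), right_chrom = character(), right_start = integer(),
    right_end = integer(), right_id = character(), label = character(),
    loop_id = character(), distance = double(), se_category = character()
  )
}

build_pair_manifest <- function(left, right, label, loop_id = NA_character_) {
  mid_l <- (left$start + left$end) %/% 2L
  mid_r <- (right$start + right$end) %/% 2L
  tibble(
    left_chrom = left$chrom, left_start = left$start, left_end = left$end,
    left_id = left$id,
    right_chrom = right$chrom, right_start = right$start,
    right_end = right$end, right_id = right$id,
    label = label, loop_id = loop_id,
    distance = ifelse(left$chrom == right$chrom,
      as.numeric(abs(mid_r - mid_l)), NA_real_
    ),
    se_category = "unassigned"
  )
}

# pools of enhancers seen on each side of the positive set
side_pools <- function(positives) {
  left <- distinct(tibble(
    chrom = positives$left_chrom, start = positives$left_start,
    end = positives$left_end, id = positives$left_id
  ))
  right <- distinct(tibble(
    chrom = positives$right_chrom, start = positives$right_start,
    end = positives$right_end, id = positives$right_id
  ))
  list(left = left, right = right)
}

# all candidate (left pool x right pool) combinations minus positives,
# minus self-pairs, deduplicated as unordered pairs; rows index into pools
candidate_negative_grid <- function(positives, same_chrom_only = FALSE) {
  pools <- side_pools(positives)
  grid <- expand.grid(
    l = seq_len(nrow(pools$left)), r = seq_len(nrow(pools$right))
  )
  lid <- pools$left$id[grid$l]
  rid <- pools$right$id[grid$r]
  key <- pair_key(lid, rid)
  pos_keys <- pair_key(positives$left_id, positives$right_id)
  keep <- lid != rid & !key %in% pos_keys & !duplicated(key)
  if (same_chrom_only) {
    keep <- keep & pools$left$chrom[grid$l] == pools$right$chrom[grid$r]
  }
  grid <- grid[keep, , drop = FALSE]
  list(grid = grid, pools = pools)
}

# orient a negative pair by coordinate (lower midpoint first on same chrom)
orient_negative <- function(left, right) {
  left <- as_tibble(left)
  right <- as_tibble(right)
  mid_l <- (left$start + left$end) %/% 2
  mid_r <- (right$start + right$end) %/% 2
  swap <- (left$chrom == right$chrom & mid_l > mid_r) |
    (left$chrom != right$chrom & left$chrom > right$chrom)
  newl <- left
  newr <- right
  newl[swap, ] <- right[swap, ]
  newr[swap, ] <- left[swap, ]
  list(left = newl, right = newr)
}

#' Random negative pairs
#'
#' Samples `n` negative pairs by randomly pairing enhancers seen on the left
#' side of the positive set with enhancers seen on the right side, explicitly
#' excluding (as unordered pairs) any combination present in the positive set,
#' with no duplicates. Negatives are oriented by coordinate.
#'
#' @param positives A positive pair manifest from [find_positive_pairs()].
#' @param n Number of negatives (default: one per positive, balanced classes).
#' @param seed Integer seed; the same seed reproduces the same negatives.
#' @return A pair manifest tibble of `n` rows labelled `negative`.
#' @export
sample_negatives_random <- function(positives, n = nrow(positives), seed = 1L) {
  stopifnot(n >= 1L, nrow(positives) > 0L)
  cand <- candidate_negative_grid(positives)
  if (nrow(cand$grid) < n) {
    abort(paste0(
      "requested ", n, " negatives but only ", nrow(cand$grid),
      " candidate pairs exist outside the positive set"
    ))
  }
  pick <- with_seed(derive_seed(seed, "neg_random"), {
    sample.int(nrow(cand$grid), n)
  })
  g <- cand$grid[pick, , drop = FALSE]
  o <- orient_negative(cand$pools$left[g$l, ], cand$pools$right[g$r, ])
  build_pair_manifest(o$left, o$right, label = "negative")
}

#' Distance-matched negative pairs
#'
#' Matches the genomic distance distribution of the positives: their distances
#' are partitioned into `n_bins` quantile intervals, and same-chromosome
#' candidate pairs are drawn so per-bin negative counts are proportional to
#' the positive bin counts. Bins with positives but no available candidates
#' are redistributed to neighbouring bins with a warning. Exclusion of
#' positives and deduplication are as in [sample_negatives_random()].
#'
#' @inheritParams sample_negatives_random
#' @param n_bins Number of distance quantile bins (default 10, deciles).
#' @return A pair manifest tibble labelled `negative` with `n` rows (or fewer,
#'   with a warning, if the candidate pool is exhausted).
#' @export
sample_negatives_distance_matched <- function(positives, n = nrow(positives),
                                              n_bins = 10L, seed = 1L) {
  stopifnot(nrow(positives) > 0L, n_bins >= 1L)
  if (anyNA(positives$distance)) {
    abort("distance-matched sampling requires intra-chromosomal positives")
  }
  cand <- candidate_negative_grid(positives, same_chrom_only = TRUE)
  g <- cand$grid
  mid_l <- (cand$pools$left$start + cand$pools$left$end)[g$l] %/% 2
  mid_r <- (cand$pools$right$start + cand$pools$right$end)[g$r] %/% 2
  cand_dist <- abs(mid_r - mid_l)

  breaks <- unique(stats::quantile(positives$distance,
    probs = seq(0, 1, length.out = n_bins + 1L), names = FALSE
  ))
  if (length(breaks) == 1L) { # all positive distances identical
    breaks <- c(breaks - 0.5, breaks + 0.5)
  }
  # assign to bins; candidates outside the positive range are unusable
  bin_of <- function(d) {
    b <- findInterval(d, breaks, rightmost.closed = TRUE)
    b[d < breaks[1] | d > breaks[length(breaks)]] <- NA_integer_
    b
  }
  nb <- length(breaks) - 1L
  pos_bin <- bin_of(positives$distance)
  cand_bin <- bin_of(cand_dist)
  target <- tabulate(pos_bin, nbins = nb)
  target <- floor(target / sum(target) * n)
  short <- n - sum(target)
  if (short > 0) { # give remainder to largest bins
    ord <- order(tabulate(pos_bin, nbins = nb), decreasing = TRUE)
    target[ord[seq_len(short)]] <- target[ord[seq_len(short)]] + 1L
  }
  avail <- tabulate(cand_bin[!is.na(cand_bin)], nbins = nb)
  deficit <- pmax(target - avail, 0L)
  if (any(deficit > 0L)) {
    warn(paste0(
      "bins with insufficient candidates; redistributing ",
      sum(deficit), " draw(s) to neighbouring bins"
    ))
    target <- pmin(target, avail)
    # push deficits to nearest bins with spare capacity
    for (b in which(deficit > 0L)) {
      need <- deficit[b]
      for (off in seq_len(nb)) {
        for (nbm in c(b - off, b + off)) {
          if (need == 0L || nbm < 1L || nbm > nb) next
          spare <- avail[nbm] - target[nbm]
          take <- min(spare, need)
          if (take > 0L) {
            target[nbm] <- target[nbm] + take
            need <- need - take
          }
        }
        if (need == 0L) break
      }
      if (need > 0L) warn("candidate pool exhausted; returning fewer negatives")
    }
  }
  picks <- with_seed(derive_seed(seed, "neg_distance"), {
    unlist(lapply(seq_len(nb), function(b) {
      rows <- which(!is.na(cand_bin) & cand_bin == b)
      if (target[b] == 0L || length(rows) == 0L) return(integer())
      rows[sample.int(length(rows), target[b])]
    }))
  })
  g <- g[picks, , drop = FALSE]
  o <- orient_negative(cand$pools$left[g$l, ], cand$pools$right[g$r, ])
  build_pair_manifest(o$left, o$right, label = "negative")
}

#' Fixed-end negative pairs
#'
#' Each negative keeps one enhancer of a sampled positive pair while the
#' partner is randomly shuffled; which side is kept alternates uniformly at
#' random. Positives are excluded as unordered pairs and duplicates removed.
#'
#' @inheritParams sample_negatives_random
#' @return A pair manifest tibble labelled `negative` with `n` rows.
#' @export
sample_negatives_fixed_end <- function(positives, n = nrow(positives), seed = 1L) {
  stopifnot(n >= 1L, nrow(positives) > 0L)
  pools <- side_pools(positives)
  pos_keys <- pair_key(positives$left_id, positives$right_id)
  with_seed(derive_seed(seed, "neg_fixed_end"), {
    seen <- character()
    out_l <- list()
    out_r <- list()
    tries <- 0L
    max_tries <- 1000L * n
    while (length(seen) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(paste0(
          "could not assemble ", n, " fixed-end negatives (",
          length(seen), " found); candidate pool too small"
        ))
      }
      i <- sample.int(nrow(positives), 1L)
      keep_left <- stats::runif(1) < 0.5
      if (keep_left) {
        kept <- tibble(
          chrom = positives$left_chrom[i], start = positives$left_start[i],
          end = positives$left_end[i], id = positives$left_id[i]
        )
        partner <- pools$right[sample.int(nrow(pools$right), 1L), ]
      } else {
        kept <- tibble(
          chrom = positives$right_chrom[i], start = positives$right_start[i],
          end = positives$right_end[i], id = positives$right_id[i]
        )
        partner <- pools$left[sample.int(nrow(pools$left), 1L), ]
      }
      if (kept$id == partner$id) next
      key <- pair_key(kept$id, partner$id)
      if (key %in% pos_keys || key %in% seen) next
      seen <- c(seen, key)
      if (keep_left) {
        out_l <- c(out_l, list(kept))
        out_r <- c(out_r, list(partner))
      } else {
        out_l <- c(out_l, list(partner))
        out_r <- c(out_r, list(kept))
      }
    }
    o <- orient_negative(bind_rows(out_l), bind_rows(out_r))
    build_pair_manifest(o$left, o$right, label = "negative")
  })
}

#' Stratified train/validation/test split
#'
#' Randomly partitions pairs into train/validation/test at the given ratio
#' (default 8:1:1), stratified by label so class balance is preserved within
#' one pair per class; partition sizes differ by at most one from the exact
#' ratio after flooring.
#'
#' @param pairs A pair manifest.
#' @param ratios Length-3 numeric vector of train/validation/test weights.
#' @param seed Integer seed.
#' @return `pairs` with a `split` column in `{train, validation, test}`.
#' @export
split_ratio <- function(pairs, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(nrow(pairs) > 0L, length(ratios) == 3L, all(ratios >= 0))
  parts <- c("train", "validation", "test")
  pairs$split <- NA_character_
  with_seed(derive_seed(seed, "split_ratio"), {
    for (lab in unique(pairs$label)) {
      idx <- sample(which(pairs$label == lab))
      n_c <- length(idx)
      exact <- n_c * ratios / sum(ratios)
      sizes <- floor(exact)
      rem <- n_c - sum(sizes)
      if (rem > 0) {
        give <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[give] <- sizes[give] + 1L
      }
      assign_to <- rep(parts, times = sizes)
      pairs$split[idx] <- assign_to
    }
  })
  pairs
}

#' Random k-fold partition
#'
#' Randomly partitions pairs into `k` folds of size differing by at most one;
#' folds are disjoint and exhaustive.
#'
#' @param pairs A pair manifest.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return `pairs` with an integer `fold` column in `1..k`.
#' @export
split_kfold <- function(pairs, k = 10L, seed = 1L) {
  if (k > nrow(pairs)) abort("k exceeds the number of pairs")
  with_seed(derive_seed(seed, "split_kfold"), {
    pairs$fold <- sample(rep_len(seq_len(k), nrow(pairs)))
  })
  pairs
}

#' Dual-constraint enhancer-level split
#'
#' Builds a test set under two leakage constraints: (i) no enhancer id occurs
#' in both train and test, and (ii) within the test set each enhancer id
#' occurs exactly once. The test set is grown greedily over a seeded random
#' pair order until `test_fraction` of pairs is reached or no admissible pair
#' remains (smaller test set returned with a warning). Pairs excluded from
#' train by constraint (i) are marked `excluded`.
#'
#' @param pairs A pair manifest.
#' @param test_fraction Target fraction of pairs in the test set.
#' @param seed Integer seed.
#' @return `pairs` with a `split` column in `{train, test, excluded}`.
#' @export
split_enhancer_level <- function(pairs, test_fraction = 0.1, seed = 1L) {
  stopifnot(nrow(pairs) > 0L, test_fraction > 0, test_fraction < 1)
  quota <- ceiling(test_fraction * nrow(pairs))
  ord <- with_seed(derive_seed(seed, "split_enh"), sample.int(nrow(pairs)))
  test_ids <- character()
  in_test <- logical(nrow(pairs))
  for (i in ord) {
    if (sum(in_test) >= quota) break
    l <- pairs$left_id[i]
    r <- pairs$right_id[i]
    if (l %in% test_ids || r %in% test_ids) next
    in_test[i] <- TRUE
    test_ids <- c(test_ids, l, r)
  }
  if (sum(in_test) < quota) {
    warn(paste0(
      "enhancer-level test quota unreachable: ", sum(in_test),
      " of ", quota, " pairs admitted"
    ))
  }
  touches_test <- pairs$left_id %in% test_ids | pairs$right_id %in% test_ids
  pairs$split <- dplyr::case_when(
    in_test ~ "test",
    touches_test ~ "excluded",
    TRUE ~ "train"
  )
  pairs
}

#' Categorize pairs by super-enhancer membership
#'
#' Assigns each pair one of three categories: `SE_intra` (both enhancers
#' overlap the same super-enhancer), `SE_inter` (each overlaps a different
#' super-enhancer), `SE_out` (otherwise). An enhancer overlapping several
#' super-enhancers is assigned to the one with the largest overlap (ties:
#' leftmost).
#'
#' @param pairs A pair manifest.
#' @param super_enhancers Tibble from [read_bed()] of super-enhancer regions.
#' @return `pairs` with `se_category` filled in.
#' @export
categorize_super_enhancer <- function(pairs, super_enhancers) {
  se_of <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(i) {
      same <- super_enhancers$chrom == chrom[i]
      ov <- pmin(super_enhancers$end, end[i]) - pmax(super_enhancers$start, start[i])
      ov[!same] <- 0L
      if (all(ov <= 0L)) return(NA_character_)
      best <- which(ov == max(ov))
      best <- best[order(super_enhancers$start[best])][1]
      super_enhancers$id[best]
    }, character(1))
  }
  se_l <- se_of(pairs$left_chrom, pairs$left_start, pairs$left_end)
  se_r <- se_of(pairs$right_chrom, pairs$right_start, pairs$right_end)
  pairs$se_category <- dplyr::case_when(
    !is.na(se_l) & !is.na(se_r) & se_l == se_r ~ "SE_intra",
    !is.na(se_l) & !is.na(se_r) ~ "SE_inter",
    TRUE ~ "SE_out"
  )
  pairs
}

#' Write / read a dataset manifest
#'
#' The manifest is a plain TSV with one row per pair (both enhancer windows,
#' label, loop id, distance, super-enhancer category and split assignment).
#'
#' @param pairs A pair manifest tibble.
#' @param path Output TSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest tibble.
#' @export
write_manifest <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
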