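#' Specification of a synthetic enhancer-interaction fixture
#'
#' The generator emulates the upstream inputs of the pipeline: a toy genome
#' whose enhancers carry planted motifs, with chromatin loops formed
#' preferentially between enhancer pairs whose sequences carry the two
#' motifs of a complementary pair (motif A on one side, motif B on the
#' other). Every same-chromosome enhancer pair inside the distance band is
#' tested against the loop rule (probability `p_pos` when the motifs
#' co-occur across the pair, `p_neg` otherwise), so interaction labels are
#' recoverable from motif content alone. Main-chromosome enhancers carry
#' exactly one of the two motifs (or neither, with probability `p_none`);
#' a small set of background enhancers on the last chromosome carries no
#' motif, providing motif-free loops and negatives. Defaults: 2 chromosomes
#' of 200 kb, 120 enhancers of 300-600 bp, motif widths 10 and 9 bp,
#' `p_pos = 0.9`, `p_neg = 0.05`.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_enhancers Total enhancer count.
#' @param bg_enhancers How many of them are motif-free background enhancers
#'   on the last chromosome.
#' @param enhancer_length Length-2 range of enhancer lengths in bp.
#' @param motif_a,motif_b Consensus strings of the planted motif pair.
#' @param p_none Probability that a main-chromosome enhancer carries no
#'   motif (otherwise it carries A or B with equal probability).
#' @param p_pos Loop probability when motifs A and B co-occur across the two
#'   sides of a pair.
#' @param p_neg Loop probability otherwise; must be `< p_pos`.
#' @param distance_range Length-2 range of candidate pair midpoint distances.
#' @param anchor_width Length-2 range of loop anchor widths in bp.
#' @param n_se Number of super-enhancer regions to emit.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(chrom_sizes = c(chr1 = 200000L, chr2 = 200000L),
                         n_enhancers = 120L, bg_enhancers = 10L,
                         enhancer_length = c(300L, 600L),
                         motif_a = "TGACGTCATC", motif_b = "CGTAAGCTG",
                         p_none = 0, p_pos = 0.9, p_neg = 0.05,
                         distance_range = c(2000L, 200000L),
                         anchor_width = c(1000L, 2000L),
                         n_se = 8L, seed = 1L) {
  if (p_pos <= p_neg) abort("p_pos must exceed p_neg")
  if (max(nchar(motif_a), nchar(motif_b)) > min(enhancer_length)) {
    abort("motif longer than the shortest enhancer")
  }
  structure(
    list(
      chrom_sizes = chrom_sizes, n_enhancers = n_enhancers,
      bg_enhancers = bg_enhancers,
      enhancer_length = enhancer_length, motif_a = toupper(motif_a),
      motif_b = toupper(motif_b), p_none = p_none, p_pos = p_pos,
      p_neg = p_neg,
      distance_range = distance_range, anchor_width = anchor_width,
      n_se = n_se, seed = seed
    ),
    class = "fixture_spec"
  )
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic fixture
#'
#' Builds the toy genome, enhancer/loop/super-enhancer annotations, a
#' variant list and a JASPAR-format motif database from a [fixture_spec()].
#' Everything derives from the spec's seed: the same spec yields
#' byte-identical files. When `dir` is given, the standard formats are
#' written there (`genome.fa`, `enhancers.bed`, `loops.bedpe`,
#' `super_enhancers.bed`, `variants.tsv`, `motifs.jaspar`, `truth.tsv`).
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional output directory (created if missing).
#' @return A list with `genome` (an `eei_genome`), `enhancers`, `loops`,
#'   `super_enhancers`, `variants`, `truth` (enhancer motif content),
#'   `spec`, and `files` (paths, when `dir` was given).
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- with_seed(derive_seed(spec$seed, "fixture"), make_fixture_impl(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      genome = file.path(dir, "genome.fa"),
      enhancers = file.path(dir, "enhancers.bed"),
      loops = file.path(dir, "loops.bedpe"),
      super_enhancers = file.path(dir, "super_enhancers.bed"),
      variants = file.path(dir, "variants.tsv"),
      motifs = file.path(dir, "motifs.jaspar"),
      truth = file.path(dir, "truth.tsv")
    )
    sset <- Biostrings::DNAStringSet(unlist(lapply(res$genome, identity)))
    Biostrings::writeXStringSet(sset, files$genome, width = 80L)
    readr::write_tsv(res$enhancers, files$enhancers, col_names = FALSE)
    readr::write_tsv(res$loops, files$loops, col_names = FALSE)
    readr::write_tsv(res$super_enhancers, files$super_enhancers,
      col_names = FALSE
    )
    readr::write_tsv(res$variants, files$variants)
    writeLines(jaspar_lines(spec), files$motifs)
    readr::write_tsv(res$truth, files$truth)
    res$files <- files
  }
  res
}

jaspar_lines <- function(spec, depth = 20L) {
  pfm_block <- function(name, consensus) {
    m <- one_hot_encode(consensus) * depth
    c(
      paste0(">", name),
      vapply(1:4, function(j) {
        paste0(
          BASES[j], " [ ",
          paste(format(m[, j], width = 3), collapse = " "), " ]"
        )
      }, character(1))
    )
  }
  c(
    pfm_block("MOTIF_A", spec$motif_a),
    pfm_block("MOTIF_B", spec$motif_b)
  )
}

make_fixture_impl <- function(spec) {
  chroms <- names(spec$chrom_sizes)
  seqs <- setNames(
    vapply(spec$chrom_sizes, rand_dna, character(1)), chroms
  )
  bg_chrom <- chroms[length(chroms)]
  main_chroms <- if (length(chroms) > 1L) chroms[-length(chroms)] else chroms
  n_main <- spec$n_enhancers - spec$bg_enhancers
  # non-overlapping enhancers on a jittered grid
  counts <- setNames(rep(0L, length(chroms)), chroms)
  counts[bg_chrom] <- spec$bg_enhancers
  main_split <- table(factor(
    sample(main_chroms, n_main, replace = TRUE), levels = main_chroms
  ))
  counts[names(main_split)] <- counts[names(main_split)] + as.integer(main_split)
  slot <- max(spec$enhancer_length) + 800L
  enh <- list()
  eid <- 0L
  for (ch in chroms) {
    n_slots <- (spec$chrom_sizes[[ch]] - 2000L) %/% slot
    take <- sort(sample.int(n_slots, min(counts[[ch]], n_slots)))
    for (s in take) {
      eid <- eid + 1L
      len <- sample(spec$enhancer_length[1]:spec$enhancer_length[2], 1L)
      start <- 1000L + (s - 1L) * slot + sample.int(200L, 1L)
      enh[[eid]] <- tibble(
        chrom = ch, start = start, end = start + len,
        id = sprintf("E%03d", eid)
      )
    }
  }
  enhancers <- bind_rows(enh)
  n_e <- nrow(enhancers)
  # main-chromosome enhancers carry exactly one motif (or none with p_none);
  # background-chromosome enhancers carry no motif
  motif_class <- ifelse(
    enhancers$chrom == bg_chrom & length(chroms) > 1L, "none",
    ifelse(stats::runif(n_e) < spec$p_none, "none",
      ifelse(stats::runif(n_e) < 0.5, "A", "B")
    )
  )
  has_a <- motif_class == "A"
  has_b <- motif_class == "B"
  # plant motifs near the enhancer midpoint so small model windows see them
  wa <- nchar(spec$motif_a)
  wb <- nchar(spec$motif_b)
  plant <- function(seqs, chrom, at, motif) {
    s <- seqs[[chrom]]
    substr(s, at + 1L, at + nchar(motif)) <- motif
    seqs[[chrom]] <- s
    seqs
  }
  pos_a <- pos_b <- rep(NA_integer_, n_e)
  for (i in seq_len(n_e)) {
    mid <- (enhancers$start[i] + enhancers$end[i]) %/% 2L
    if (has_a[i]) {
      pos_a[i] <- mid - wa - 3L
      seqs <- plant(seqs, enhancers$chrom[i], pos_a[i], spec$motif_a)
    }
    if (has_b[i]) {
      pos_b[i] <- mid + 4L
      seqs <- plant(seqs, enhancers$chrom[i], pos_b[i], spec$motif_b)
    }
  }
  truth <- mutate(enhancers,
    has_a = has_a, has_b = has_b, pos_a = pos_a, pos_b = pos_b
  )
  # every same-chromosome pair within the distance band is tested against
  # the loop rule, so non-loop pairs are genuine stochastic failures
  mids <- (enhancers$start + enhancers$end) %/% 2L
  cand <- list()
  for (ch in chroms) {
    idx <- which(enhancers$chrom == ch)
    if (length(idx) < 2L) next
    grid <- utils::combn(idx, 2L)
    d <- abs(mids[grid[1, ]] - mids[grid[2, ]])
    keep <- d >= spec$distance_range[1] & d <= spec$distance_range[2]
    cand[[ch]] <- tibble(i = grid[1, keep], j = grid[2, keep])
  }
  cand <- bind_rows(cand)
  # orientation by coordinate; loop forms by motif co-occurrence
  lo <- ifelse(mids[cand$i] <= mids[cand$j], cand$i, cand$j)
  hi <- ifelse(mids[cand$i] <= mids[cand$j], cand$j, cand$i)
  co_occur <- (has_a[lo] & has_b[hi]) | (has_b[lo] & has_a[hi])
  p_loop <- ifelse(co_occur, spec$p_pos, spec$p_neg)
  formed <- stats::runif(nrow(cand)) < p_loop
  anchor_around <- function(i) {
    w <- sample(spec$anchor_width[1]:spec$anchor_width[2], length(i),
      replace = TRUE
    )
    mid <- mids[i]
    tibble(
      start = pmax(0L, as.integer(mid - w %/% 2L)),
      end = as.integer(mid + w %/% 2L)
    )
  }
  al <- anchor_around(lo[formed])
  ar <- anchor_around(hi[formed])
  loops <- tibble(
    chrom1 = enhancers$chrom[lo[formed]], start1 = al$start, end1 = al$end,
    chrom2 = enhancers$chrom[hi[formed]], start2 = ar$start, end2 = ar$end,
    loop_id = sprintf("L%04d", seq_len(sum(formed)))
  )
  # super-enhancers spanning runs of 2-3 adjacent enhancers
  se <- list()
  for (k in seq_len(spec$n_se)) {
    ch <- chroms[1L + (k - 1L) %% length(chroms)]
    idx <- which(enhancers$chrom == ch)
    if (length(idx) < 3L) next
    first <- sample.int(length(idx) - 2L, 1L)
    members <- idx[first:(first + sample(1:2, 1L) + 0L)]
    se[[k]] <- tibble(
      chrom = ch,
      start = min(enhancers$start[members]) - 200L,
      end = max(enhancers$end[members]) + 200L,
      id = sprintf("SE%02d", k)
    )
  }
  super_enhancers <- bind_rows(se)
  # variants: effect variants hit planted motif A bases, nulls hit background
  eff_src <- which(has_a)
  eff_src <- eff_src[seq_len(min(5L, length(eff_src)))]
  variants <- list()
  for (i in eff_src) {
    p0 <- pos_a[i] + 4L # 0-based position inside the planted motif
    ref <- substr(seqs[[enhancers$chrom[i]]], p0 + 1L, p0 + 1L)
    variants[[length(variants) + 1L]] <- tibble(
      chrom = enhancers$chrom[i], pos = p0 + 1L, ref = ref,
      alt = sample(setdiff(BASES, ref), 1L), type = "effect",
      enhancer = enhancers$id[i]
    )
  }
  for (k in seq_len(5L)) {
    ch <- sample(chroms, 1L)
    repeat {
      p0 <- sample.int(spec$chrom_sizes[[ch]] - 400L, 1L) + 200L
      near <- any(enhancers$chrom == ch &
        abs((enhancers$start + enhancers$end) %/% 2L - p0) < 2000L)
      if (!near) break
    }
    ref <- substr(seqs[[ch]], p0 + 1L, p0 + 1L)
    variants[[length(variants) + 1L]] <- tibble(
      chrom = ch, pos = p0 + 1L, ref = ref,
      alt = sample(setdiff(BASES, ref), 1L), type = "null",
      enhancer = NA_character_
    )
  }
  genome <- structure(
    as.list(seqs),
    sizes = setNames(nchar(seqs), chroms), class = "eei_genome"
  )
  list(
    genome = genome, enhancers = enhancers, loops = loops,
    super_enhancers = super_enhancers, variants = bind_rows(variants),
    truth = truth, spec = spec
  )
}

#' Build a labelled, split dataset manifest from a fixture
#'
#' Convenience composition of the dataset pipeline on a fixture: positive
#' pairs by anchor containment, negatives by the chosen strategy (1:1 with
#' positives), and a split assignment.
#'
#' @param fixture Result of [make_fixture()].
#' @param neg_strategy `"random"`, `"distance"` or `"fixed_end"`.
#' @param split `"ratio"` (8:1:1), `"kfold"` or `"enhancer_level"`.
#' @param seed Integer seed.
#' @return A pair manifest tibble with `split` (or `fold`) column.
#' @export
fixture_dataset <- function(fixture, neg_strategy = "random", split = "ratio",
                            seed = 1L) {
  pos <- find_positive_pairs(fixture$loops, fixture$enhancers)
  neg <- switch(neg_strategy,
    random = sample_negatives_random(pos, seed = seed),
    distance = sample_negatives_distance_matched(pos, seed = seed),
    fixed_end = sample_negatives_fixed_end(pos, seed = seed),
    abort(paste0("unknown negative strategy: ", neg_strategy))
  )
  pairs <- bind_rows(pos, neg)
  switch(split,
    ratio = split_ratio(pairs, seed = seed),
    kfold = split_kfold(pairs, seed = seed),
    enhancer_level = split_enhancer_level(pairs, seed = seed),
    abort(paste0("unknown split: ", split))
  )
}

#' Deterministic surrogate scorers for perturbation analyses
#'
#' Builds closed-form scorers satisfying the model's predict contract
#' (`function(left_seq, right_seq) -> probability`), used as oracles for the
#' greedy search and synergy statistics.
#'
#' * `constant`: always returns `value`.
#' * `additive`: `0.05 + 0.9 * sum(w_i * intact_i) / sum(w)` where region `i`
#'   of the reference pair is intact iff its sequence content is unchanged;
#'   `weights_left`/`weights_right` give one weight per `region_size` block.
#' * `and_gate`: returns `hi` while at least one of the two designated
#'   regions still carries its reference content and `lo` only when both are
#'   disrupted, so the prediction drops only under joint perturbation.
#' * `motif`: returns `hi` iff a motif pair co-occurs across the two
#'   sequences (`motif_a` on one side and `motif_b` on the other), else `lo`.
#'
#' @param kind One of `"constant"`, `"additive"`, `"and_gate"`, `"motif"`.
#' @param left_ref,right_ref Reference sequences (additive / and_gate).
#' @param region_size Region width for `additive`.
#' @param weights_left,weights_right Region weights for `additive`.
#' @param left_region,right_region `c(start, end)` designated regions for
#'   `and_gate`.
#' @param motif_a,motif_b Motif strings for `motif`.
#' @param value Constant value for `constant`.
#' @param hi,lo High/low outputs for gate-type scorers.
#' @return A vectorized scorer function.
#' @export
make_surrogate_scorer <- function(kind = c("constant", "additive", "and_gate", "motif"),
                                  left_ref = NULL, right_ref = NULL,
                                  region_size = NULL,
                                  weights_left = NULL, weights_right = NULL,
                                  left_region = NULL, right_region = NULL,
                                  motif_a = NULL, motif_b = NULL,
                                  value = 0.5, hi = 0.99, lo = 0.01) {
  kind <- match.arg(kind)
  region_content <- function(s, start, end) substr(s, start + 1L, end)
  switch(kind,
    constant = function(left_seq, right_seq) {
      rep(value, length(left_seq))
    },
    additive = {
      stopifnot(!is.null(left_ref), !is.null(right_ref), !is.null(region_size))
      nl <- nchar(left_ref) %/% region_size
      nr <- nchar(right_ref) %/% region_size
      stopifnot(
        length(weights_left) == nl, length(weights_right) == nr,
        all(is.finite(c(weights_left, weights_right)))
      )
      wsum <- sum(weights_left) + sum(weights_right)
      function(left_seq, right_seq) {
        vapply(seq_along(left_seq), function(b) {
          sc <- 0
          for (i in seq_len(nl)) {
            sc <- sc + weights_left[i] *
              (region_content(left_seq[b], (i - 1L) * region_size, i * region_size) ==
                region_content(left_ref, (i - 1L) * region_size, i * region_size))
          }
          for (i in seq_len(nr)) {
            sc <- sc + weights_right[i] *
              (region_content(right_seq[b], (i - 1L) * region_size, i * region_size) ==
                region_content(right_ref, (i - 1L) * region_size, i * region_size))
          }
          0.05 + 0.9 * sc / wsum
        }, numeric(1))
      }
    },
    and_gate = {
      stopifnot(
        !is.null(left_ref), !is.null(right_ref),
        !is.null(left_region), !is.null(right_region)
      )
      ref_l <- region_content(left_ref, left_region[1], left_region[2])
      ref_r <- region_content(right_ref, right_region[1], right_region[2])
      function(left_seq, right_seq) {
        li <- vapply(left_seq, function(s) {
          region_content(s, left_region[1], left_region[2]) == ref_l
        }, logical(1), USE.NAMES = FALSE)
        ri <- vapply(right_seq, function(s) {
          region_content(s, right_region[1], right_region[2]) == ref_r
        }, logical(1), USE.NAMES = FALSE)
        ifelse(li | ri, hi, lo)
      }
    },
    motif = {
      stopifnot(!is.null(motif_a), !is.null(motif_b))
      function(left_seq, right_seq) {
        al <- grepl(motif_a, left_seq, fixed = TRUE)
        bl <- grepl(motif_b, left_seq, fixed = TRUE)
        ar <- grepl(motif_a, right_seq, fixed = TRUE)
        br <- grepl(motif_b, right_seq, fixed = TRUE)
        ifelse((al & br) | (bl & ar), hi, lo)
      }
    }
  )
}
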