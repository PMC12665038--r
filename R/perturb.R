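split_regions <- function(seq_len, region_size, side) {
  if (seq_len %% region_size != 0L) {
    abort("region_size must divide the sequence length")
  }
  nr <- seq_len %/% region_size
  tibble(
    side = side,
    region = seq_len(nr),
    start = (seq_len(nr) - 1L) * region_size,
    end = seq_len(nr) * region_size
  )
}

# mean score over n_shuffles dinucleotide shuffles of one candidate region,
# applied on top of the current (possibly already perturbed) pair; returns
# replicate scores and the first replicate's perturbed sequence
perturb_candidate <- function(scorer, cur_l, cur_r, side, start, end,
                              n_shuffles) {
  ls <- character(n_shuffles)
  rs <- character(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    if (side == "left") {
      ls[k] <- shuffle_region(cur_l, start, end)
      rs[k] <- cur_r
    } else {
      ls[k] <- cur_l
      rs[k] <- shuffle_region(cur_r, start, end)
    }
  }
  list(scores = scorer(ls, rs), first_l = ls[1], first_r = rs[1])
}

#' Greedy search for functional regions of an interacting pair
#'
#' Divides both sequences into non-overlapping regions and iteratively
#' perturbs them: at each iteration every remaining candidate region (both
#' sides pooled) is dinucleotide-shuffled `n_shuffles` times on top of the
#' current, already-perturbed pair, and the region whose perturbation
#' optimizes the objective (largest prediction drop for `maximize_drop`) is
#' permanently retained (its first shuffled replicate) and removed from the
#' candidate pool. Ties are broken by the leftmost region, left side before
#' right. Each candidate's delta is `baseline - mean(replicate scores)`,
#' where the baseline is re-scored at the start of every iteration.
#'
#' @param scorer A scorer `function(left_seq, right_seq) -> probability`
#'   ([etnet_scorer()] or [make_surrogate_scorer()]).
#' @param left_seq,right_seq The unperturbed pair of DNA strings.
#' @param region_size Region width in bp (default 100; must divide the
#'   sequence length).
#' @param n_shuffles Shuffle replicates per candidate per iteration
#'   (default 10).
#' @param max_iters Number of regions to select (default: all; clipped with a
#'   warning if larger).
#' @param objective `"maximize_drop"` or `"minimize_drop"`.
#' @param seed Integer seed.
#' @return An `eei_greedy` tibble: one row per candidate per iteration with
#'   `iteration`, `side`, `region`, `start`, `end`, `baseline`, `delta`,
#'   `deltas` (list column of replicate deltas) and `selected`.
#' @export
greedy_region_search <- function(scorer, left_seq, right_seq,
                                 region_size = 100L, n_shuffles = 10L,
                                 max_iters = NULL,
                                 objective = c("maximize_drop", "minimize_drop"),
                                 seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(n_shuffles >= 1L)
  cand <- bind_rows(
    split_regions(nchar(left_seq), region_size, "left"),
    split_regions(nchar(right_seq), region_size, "right")
  )
  # candidate order encodes the tie-break: left side first, then leftmost
  cand <- arrange(cand, factor(.data$side, levels = c("left", "right")), .data$start)
  total <- nrow(cand)
  if (is.null(max_iters)) max_iters <- total
  if (max_iters > total) {
    warn("max_iters exceeds the number of regions; clipped")
    max_iters <- total
  }
  cur_l <- left_seq
  cur_r <- right_seq
  remaining <- rep(TRUE, total)
  records <- list()
  with_seed(derive_seed(seed, "greedy"), {
    for (iter in seq_len(max_iters)) {
      baseline <- scorer(cur_l, cur_r)
      idxs <- which(remaining)
      res <- purrr::map(idxs, function(i) {
        perturb_candidate(
          scorer, cur_l, cur_r, cand$side[i], cand$start[i], cand$end[i],
          n_shuffles
        )
      })
      deltas <- vapply(res, function(r) baseline - mean(r$scores), numeric(1))
      best_pos <- if (objective == "maximize_drop") {
        which(deltas == max(deltas))[1]
      } else {
        which(deltas == min(deltas))[1]
      }
      rep_deltas <- purrr::map(res, function(r) baseline - r$scores)
      records[[iter]] <- tibble(
        iteration = iter,
        side = cand$side[idxs], region = cand$region[idxs],
        start = cand$start[idxs], end = cand$end[idxs],
        baseline = baseline, delta = deltas,
        deltas = rep_deltas,
        selected = seq_along(idxs) == best_pos
      )
      sel <- res[[best_pos]]
      cur_l <- sel$first_l
      cur_r <- sel$first_r
      remaining[idxs[best_pos]] <- FALSE
    }
  })
  structure(bind_rows(records),
    class = c("eei_greedy", class(tibble())),
    objective = objective, region_size = region_size
  )
}

#' Top-scoring regions of a greedy search
#' @param x An `eei_greedy` result.
#' @return The selected rows, in selection order.
#' @export
selected_regions <- function(x) {
  stopifnot(inherits(x, "eei_greedy"))
  filter(as_tibble(x), .data$selected)
}

#' @export
autoplot.eei_greedy <- function(object, ...) {
  sel <- selected_regions(object)
  sel$label <- paste0(sel$side, ":", sel$start, "-", sel$end)
  ggplot(sel, aes(
    x = stats::reorder(.data$label, .data$iteration),
    y = .data$delta, fill = .data$side
  )) +
    geom_col() +
    labs(x = "Selected region (by iteration)", y = "Prediction drop") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Super-additivity of one region pair
#'
#' Quantifies the interaction between one region per side: `delta_left`,
#' `delta_right` and `delta_joint` are prediction drops (baseline minus mean
#' over `n_shuffles` replicates) under left-only, right-only and joint
#' perturbation (joint replicates pair the same shuffles as the individual
#' runs). The synergy statistic is
#' `S = delta_joint - (delta_left + delta_right)`; the pair is classified
#' super-additive iff `S > tau`.
#'
#' @inheritParams greedy_region_search
#' @param region_left,region_right Length-2 integer vectors `c(start, end)`
#'   (0-based half-open) within each sequence.
#' @param tau Super-additivity tolerance (default 0).
#' @return An `eei_synergy` one-row tibble with the three deltas, `synergy`
#'   and `classification`.
#' @export
synergy <- function(scorer, left_seq, right_seq, region_left, region_right,
                    n_shuffles = 10L, tau = 0, seed = 1L) {
  with_seed(derive_seed(seed, "synergy"), {
    baseline <- scorer(left_seq, right_seq)
    shuf_l <- vapply(seq_len(n_shuffles), function(k) {
      shuffle_region(left_seq, region_left[1], region_left[2])
    }, character(1))
    shuf_r <- vapply(seq_len(n_shuffles), function(k) {
      shuffle_region(right_seq, region_right[1], region_right[2])
    }, character(1))
    d_left <- baseline - mean(scorer(shuf_l, rep(right_seq, n_shuffles)))
    d_right <- baseline - mean(scorer(rep(left_seq, n_shuffles), shuf_r))
    d_joint <- baseline - mean(scorer(shuf_l, shuf_r))
    s <- d_joint - (d_left + d_right)
    structure(
      tibble(
        baseline = baseline, delta_left = d_left, delta_right = d_right,
        delta_joint = d_joint, synergy = s,
        classification = ifelse(s > tau, "super-additive", "additive-or-sub-additive"),
        n_shuffles = n_shuffles
      ),
      class = c("eei_synergy", class(tibble()))
    )
  })
}

# best single region on one side by prediction drop (top-1 greedy step)
top_region <- function(scorer, left_seq, right_seq, side, region_size,
                       n_shuffles) {
  regions <- split_regions(
    nchar(if (side == "left") left_seq else right_seq), region_size, side
  )
  deltas <- vapply(seq_len(nrow(regions)), function(i) {
    pc <- perturb_candidate(
      scorer, left_seq, right_seq, side, regions$start[i], regions$end[i],
      n_shuffles
    )
    scorer(left_seq, right_seq) - mean(pc$scores)
  }, numeric(1))
  best <- which(deltas == max(deltas))[1]
  c(regions$start[best], regions$end[best])
}

#' Survey super-additivity across a set of pairs
#'
#' For every pair, identifies one focal region per side (the top-1 greedy
#' region by prediction drop, or the whole sequence with
#' `region_mode = "whole"`), computes the synergy statistic, and correlates
#' synergy strength with pairwise sequence similarity (cosine similarity of
#' 4-mer count vectors of the two sequences).
#'
#' @inheritParams synergy
#' @param pairs A tibble with character columns `left_seq` and `right_seq`.
#' @param region_size Region width for the top-1 search (default 100).
#' @param region_mode `"greedy_top1"` (default) or `"whole"`.
#' @return An `eei_synergy_survey` object: list with `per_pair` tibble
#'   (deltas, synergy, classification, similarity), `fraction_super`,
#'   `correlation` (Pearson r), `p_value`.
#' @export
synergy_survey <- function(scorer, pairs, region_size = 100L, n_shuffles = 10L,
                           tau = 0, seed = 1L,
                           region_mode = c("greedy_top1", "whole")) {
  region_mode <- match.arg(region_mode)
  stopifnot(nrow(pairs) >= 2L)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    l <- pairs$left_seq[i]
    r <- pairs$right_seq[i]
    sd_i <- derive_seed(seed, paste0("survey", i))
    if (region_mode == "whole") {
      rl <- c(0L, nchar(l))
      rr <- c(0L, nchar(r))
    } else {
      with_seed(sd_i, {
        rl <- top_region(scorer, l, r, "left", region_size, n_shuffles)
        rr <- top_region(scorer, l, r, "right", region_size, n_shuffles)
      })
    }
    syn <- synergy(scorer, l, r, rl, rr, n_shuffles, tau, seed = sd_i)
    syn$similarity <- kmer_cosine(l, r, k = 4L)
    syn$pair <- i
    syn
  })
  per_pair <- bind_rows(rows)
  frac <- mean(per_pair$classification == "super-additive")
  if (stats::sd(per_pair$similarity) == 0 || stats::sd(per_pair$synergy) == 0) {
    warn("constant synergy or similarity; correlation undefined")
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(per_pair$synergy, per_pair$similarity,
      method = "pearson", alternative = "two.sided"
    )
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(
      per_pair = per_pair, fraction_super = frac,
      correlation = r, p_value = p, tau = tau
    ),
    class = "eei_synergy_survey"
  )
}

#' @export
print.eei_synergy_survey <- function(x, ...) {
  cat(
    "<eei_synergy_survey> ", nrow(x$per_pair), " pairs; ",
    sprintf("%.1f%%", 100 * x$fraction_super), " super-additive; ",
    "r(synergy, similarity) = ", signif(x$correlation, 3),
    " (p = ", signif(x$p_value, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.eei_synergy_survey <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$per_pair), fraction_super = x$fraction_super,
    correlation = x$correlation, p_value = x$p_value
  )
}

#' @export
autoplot.eei_synergy_survey <- function(object, ...) {
  ggplot(object$per_pair, aes(x = .data$similarity, y = .data$synergy)) +
    geom_point(aes(colour = .data$classification)) +
    labs(x = "Sequence similarity (4-mer cosine)", y = "Synergy S") +
    theme_bw()
}

# cosine similarity of k-mer count vectors of two sequences
kmer_cosine <- function(a, b, k = 4L) {
  fa <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(a), k)
  fb <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(b), k)
  den <- sqrt(sum(fa^2)) * sqrt(sum(fb^2))
  if (den == 0) return(NA_real_)
  sum(fa * fb) / den
}
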