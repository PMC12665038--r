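#' Construct a position-weight-matrix motif
#'
#' @param name Motif name.
#' @param mat A `w x 4` non-negative matrix (columns A, C, G, T); rows are
#'   normalized to sum to 1 (all-zero rows become uniform).
#' @param source `"attribution"` or `"database"`.
#' @param nsites Occurrence count backing the matrix.
#' @return A `pwm_motif` object.
#' @export
pwm_motif <- function(name, mat, source = "database", nsites = 1L) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L, all(mat >= 0))
  rs <- rowSums(mat)
  mat[rs == 0, ] <- 0.25
  rs[rs == 0] <- 1
  mat <- mat / rs
  colnames(mat) <- BASES
  structure(
    list(name = name, mat = mat, source = source, nsites = as.integer(nsites)),
    class = "pwm_motif"
  )
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(
    "<pwm_motif> ", x$name, " (w = ", nrow(x$mat), ", source = ", x$source,
    ", nsites = ", x$nsites, ")\n",
    sep = ""
  )
  invisible(x)
}

motif_width <- function(m) nrow(m$mat)

consensus_string <- function(m) {
  paste(BASES[max.col(m$mat, ties.method = "first")], collapse = "")
}

#' Read a JASPAR PFM motif database
#'
#' Parses JASPAR-style position frequency matrices: a `>ID name` header
#' followed by four rows (A, C, G, T order), either bare numbers or the
#' bracketed `A [ 1 2 3 ]` form. Counts are kept as `nsites` (the per-motif
#' maximum column sum) and normalized per position.
#'
#' @param path Path to a JASPAR PFM file.
#' @return A list of `pwm_motif` objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) abort("no motif headers found in JASPAR file")
  purrr::map(seq_along(heads), function(i) {
    h <- heads[i]
    stopifnot(h + 4L <= length(lines))
    name <- trimws(sub("^>", "", lines[h]))
    name <- gsub("\\s+", "_", name)
    rows <- lapply(lines[(h + 1L):(h + 4L)], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[", "", ln)
      ln <- gsub("\\]", "", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) abort(paste0("ragged PFM rows for motif ", name))
    counts <- t(do.call(rbind, rows)) # w x 4
    pwm_motif(name, counts, source = "database",
      nsites = max(1L, round(max(rowSums(counts))))
    )
  })
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A list of `pwm_motif` objects.
#' @param path Output path.
#' @param background Background letter frequencies (length 4, A/C/G/T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(
      sprintf("%s %.5f", BASES, background),
      collapse = " "
    ), ""
  ), con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$mat), m$nsites
    ), con)
    writeLines(apply(m$mat, 1L, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal file
#'
#' @param path Path to a MEME-format motif file.
#' @return A list of `pwm_motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (length(starts) == 0L) abort("no MOTIF blocks found in MEME file")
  purrr::map(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr_i <- s + grep("letter-probability matrix",
      lines[(s + 1L):min(s + 5L, length(lines))]
    )[1]
    hdr <- lines[hdr_i]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else {
      1L
    }
    rows <- lines[(hdr_i + 1L):(hdr_i + w)]
    mat <- do.call(rbind, lapply(rows, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }))
    pwm_motif(name, mat, source = "database", nsites = nsites)
  })
}

# non-overlapping high-importance windows of one importance vector
importance_peaks <- function(importance, window, quantile_thr) {
  L <- length(importance)
  if (L < window) return(integer())
  ws <- as.numeric(stats::filter(importance, rep(1, window), sides = 1))
  ws <- ws[window:L] # score of window starting at i = ws[i], i = 1..L-window+1
  thr <- stats::quantile(ws, quantile_thr, names = FALSE)
  cand <- which(ws > thr) # strict: flat tracks yield no peaks
  cand <- cand[order(ws[cand], decreasing = TRUE)]
  chosen <- integer()
  for (i in cand) {
    if (!any(abs(chosen - i) < window)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

#' Convert attribution tracks to candidate PWM motifs
#'
#' Slides a window of width `window` over each side's per-position importance
#' track, keeps windows whose summed importance exceeds the `quantile_thr`
#' quantile of all window scores on that track (strictly, so flat tracks
#' yield nothing), merges overlapping windows (best-scoring first), and
#' builds a PWM from the positive attribution mass in each retained window,
#' normalized per position.
#'
#' @param tracks An `eei_attribution` or list of them.
#' @param window Window width in bp; when matching against a database, use
#'   the mean database motif length (see [mean_motif_width()]).
#' @param quantile_thr Importance quantile threshold (default 0.95).
#' @return A list of `pwm_motif` objects (possibly empty).
#' @export
attribution_to_pwms <- function(tracks, window, quantile_thr = 0.95) {
  if (inherits(tracks, "eei_attribution")) tracks <- list(tracks)
  out <- list()
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    for (side in c("left", "right")) {
      imp <- tr[[paste0(side, "_importance")]]
      contrib <- tr[[side]]
      for (s in importance_peaks(imp, window, quantile_thr)) {
        rows <- s:(s + window - 1L)
        out[[length(out) + 1L]] <- pwm_motif(
          sprintf("track%d_%s_%d", ti, side, s - 1L),
          pmax(contrib[rows, , drop = FALSE], 0),
          source = "attribution"
        )
      }
    }
  }
  out
}

#' Mean motif width of a database, rounded
#' @param database List of `pwm_motif`s.
#' @return Integer mean width.
#' @export
mean_motif_width <- function(database) {
  as.integer(round(mean(vapply(database, motif_width, numeric(1)))))
}

reverse_complement_pwm <- function(mat) {
  mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

# max cosine similarity over all full-overlap offsets of the shorter motif
pwm_cosine <- function(a, b) {
  if (nrow(a) > nrow(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  w <- nrow(a)
  best <- -Inf
  va <- as.vector(a)
  na <- sqrt(sum(va^2))
  if (na == 0) return(0)
  for (off in 0:(nrow(b) - w)) {
    vb <- as.vector(b[(off + 1L):(off + w), , drop = FALSE])
    nb <- sqrt(sum(vb^2))
    if (nb == 0) next
    best <- max(best, sum(va * vb) / (na * nb))
  }
  best
}

#' Match query PWMs against a motif database
#'
#' For each query, finds the best database motif by maximum cosine similarity
#' over all alignment offsets (forward orientation by default; set
#' `both_orientations` to also scan the reverse complement) and retains the
#' match iff the similarity reaches `threshold`. Per-database-motif
#' occurrence counts are aggregated over all retained queries and can be
#' written as a MEME minimal file with `nsites` set to the counts.
#'
#' @param queries List of query `pwm_motif`s (e.g. from
#'   [attribution_to_pwms()]).
#' @param database List of database `pwm_motif`s (from [read_jaspar_pfm()] or
#'   [read_meme()]).
#' @param threshold Cosine similarity threshold (default 0.8).
#' @param both_orientations Also scan reverse complements (default `FALSE`).
#' @param meme_out Optional path; when set, the matched database motifs are
#'   written there in MEME format with occurrence counts.
#' @return An `eei_motif_matches` object: list with `matches` (one row per
#'   query: best motif, similarity, retained) and `counts` (occurrences per
#'   database motif among retained matches).
#' @export
match_motifs <- function(queries, database, threshold = 0.8,
                         both_orientations = FALSE, meme_out = NULL) {
  if (length(database) == 0L) abort("empty motif database")
  rows <- purrr::map(seq_along(queries), function(i) {
    q <- queries[[i]]
    sims <- vapply(database, function(d) {
      s <- pwm_cosine(q$mat, d$mat)
      if (both_orientations) {
        s <- max(s, pwm_cosine(q$mat, reverse_complement_pwm(d$mat)))
      }
      s
    }, numeric(1))
    best <- which.max(sims)
    tibble(
      query = q$name, match = database[[best]]$name,
      similarity = sims[best], retained = sims[best] >= threshold
    )
  })
  matches <- bind_rows(rows)
  counts <- matches |>
    filter(.data$retained) |>
    dplyr::count(.data$match, name = "occurrences") |>
    arrange(dplyr::desc(.data$occurrences))
  out <- structure(
    list(matches = matches, counts = counts, threshold = threshold),
    class = "eei_motif_matches"
  )
  if (!is.null(meme_out)) {
    by_name <- setNames(database, vapply(database, function(d) d$name, character(1)))
    hits <- purrr::map(seq_len(nrow(counts)), function(i) {
      m <- by_name[[counts$match[i]]]
      m$nsites <- counts$occurrences[i]
      m
    })
    write_meme(hits, meme_out)
  }
  out
}

#' @export
print.eei_motif_matches <- function(x, ...) {
  cat(
    "<eei_motif_matches> ", nrow(x$matches), " queries, ",
    sum(x$matches$retained), " retained at threshold ", x$threshold, "\n",
    sep = ""
  )
  if (nrow(x$counts) > 0L) print(utils::head(x$counts, 10L))
  invisible(x)
}

#' @export
tidy.eei_motif_matches <- function(x, ...) x$matches
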