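#' Read a genome FASTA into a random-access handle
#'
#' Loads a (multi-)FASTA file and returns a genome handle giving random access
#' to any subsequence by `(chrom, start, end)` in 0-based half-open
#' coordinates. Sequences are uppercased on load; positions outside the
#' chromosome yield `N`, so windows overhanging chromosome ends are padded
#' rather than shifted.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `eei_genome`: a named list of chromosome
#'   sequences (as single strings) with a `sizes` attribute.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- read_genome(fa)
#' genome_sequence(g, "chr1", 0, 4)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(paste0(
      "duplicate chromosome names in FASTA: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  seqs <- setNames(toupper(as.character(ss)), nm)
  structure(
    as.list(seqs),
    sizes = setNames(nchar(seqs), nm),
    class = "eei_genome"
  )
}

#' @export
print.eei_genome <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat("<eei_genome> ", length(sz), " chromosome(s), ",
    format(sum(sz), big.mark = ","), " bp total\n",
    sep = ""
  )
  invisible(x)
}

#' Chromosome sizes of a genome handle
#' @param genome An `eei_genome`.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_sizes <- function(genome) {
  stopifnot(inherits(genome, "eei_genome"))
  attr(genome, "sizes")
}

#' Extract a subsequence, padding out-of-range positions with N
#'
#' @param genome An `eei_genome` handle from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; `start` may be negative and
#'   `end` may exceed the chromosome length, in which case the clipped part is
#'   returned as `N`.
#' @return A character scalar of length `end - start`.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "eei_genome"))
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome not present in genome: ", chrom))
  }
  if (end <= start) abort("end must be > start")
  len <- attr(genome, "sizes")[[chrom]]
  lo <- min(max(start, 0L), len)
  hi <- max(min(end, len), lo)
  core <- if (hi > lo) substr(genome[[chrom]], lo + 1L, hi) else ""
  left_pad <- max(0L, min(lo, end) - start)
  right_pad <- (end - start) - left_pad - (hi - lo)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

parse_coord_cols <- function(df, cols, path) {
  for (cc in cols) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v) && !all(is.na(df[[cc]]))) {
      abort(paste0("non-integer coordinates in ", path, " column ", cc))
    }
    if (anyNA(v)) abort(paste0("non-integer coordinates in ", path))
    df[[cc]] <- v
  }
  df
}

#' Read a BED file of genomic regions
#'
#' Parses BED3+ (tab-separated, 0-based half-open, coordinates preserved
#' verbatim). The name column is used as the region id when present, otherwise
#' ids default to `"chrom:start-end"`. Records with `start >= end` are dropped
#' with a warning.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`.
#' @export
read_bed <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE
  ))
  if (ncol(df) < 3L) abort(paste0("BED file needs >= 3 columns: ", path))
  df <- parse_coord_cols(df, c("X2", "X3"), path)
  out <- tibble(
    chrom = df$X1, start = df$X2, end = df$X3,
    id = if (ncol(df) >= 4L) df$X4 else NA_character_
  )
  out$id <- ifelse(is.na(out$id) | out$id == ".",
    paste0(out$chrom, ":", out$start, "-", out$end), out$id
  )
  bad <- out$start >= out$end | out$start < 0L
  if (any(bad)) {
    warn(paste0(sum(bad), " BED record(s) with start >= end or start < 0 dropped"))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Read a BEDPE file of chromatin interaction loops
#'
#' Parses BEDPE (>= 6 tab-separated columns; column 7, when present, is the
#' loop id). Coordinates are 0-based half-open and preserved verbatim.
#' Cross-chromosome loops and records with invalid anchors are rejected with a
#' warning; only intra-chromosomal loops are retained.
#'
#' @param path Path to a BEDPE file.
#' @return A tibble with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `loop_id`.
#' @export
read_bedpe <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE
  ))
  if (ncol(df) < 6L) abort(paste0("BEDPE file needs >= 6 columns: ", path))
  df <- parse_coord_cols(df, c("X2", "X3", "X5", "X6"), path)
  out <- tibble(
    chrom1 = df$X1, start1 = df$X2, end1 = df$X3,
    chrom2 = df$X4, start2 = df$X5, end2 = df$X6,
    loop_id = if (ncol(df) >= 7L) df$X7 else NA_character_
  )
  out$loop_id <- ifelse(is.na(out$loop_id) | out$loop_id == ".",
    paste0("loop", seq_len(nrow(out))), out$loop_id
  )
  bad_anchor <- out$start1 >= out$end1 | out$start2 >= out$end2 |
    out$start1 < 0L | out$start2 < 0L
  if (any(bad_anchor)) {
    warn(paste0(sum(bad_anchor), " BEDPE record(s) with invalid anchors dropped"))
    out <- out[!bad_anchor, , drop = FALSE]
  }
  cross <- out$chrom1 != out$chrom2
  if (any(cross)) {
    warn(paste0(sum(cross), " cross-chromosome loop(s) rejected"))
    out <- out[!cross, , drop = FALSE]
  }
  out
}

#' Standardize regions to a fixed window centered on their midpoints
#'
#' Each region is replaced by a window of `width` bp centered on
#' `floor((start + end) / 2)`. Negative start coordinates are allowed in the
#' result; sequence extraction pads out-of-chromosome positions with `N`, so
#' the midpoint stays anchored. Idempotent for regions already of the target
#' width.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (and any other columns,
#'   which are preserved).
#' @param width Target window size in bp (even, > 0); default 2000.
#' @return The input tibble with `start`/`end` replaced by the standardized
#'   window.
#' @export
standardize_window <- function(regions, width = 2000L) {
  stopifnot(width > 0L, width %% 2L == 0L)
  mid <- (regions$start + regions$end) %/% 2L
  regions$start <- as.integer(mid - width %/% 2L)
  regions$end <- as.integer(mid + width %/% 2L)
  regions
}

#' One-hot encode a DNA sequence
#'
#' Maps each base to a binary row vector with columns ordered A, C, G, T:
#' `A = (1,0,0,0)`, `C = (0,1,0,0)`, `G = (0,0,1,0)`, `T = (0,0,0,1)`;
#' ambiguous bases (`N` and, with a warning, anything else) encode as the
#' all-zero row. Input is uppercased first.
#'
#' @param sequence A DNA string.
#' @return An `L x 4` binary matrix with colnames `A`, `C`, `G`, `T`.
#' @examples
#' one_hot_encode("ACGTN")
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) abort("cannot encode an empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)
  if (anyNA(idx) && any(chars[is.na(idx)] != "N")) {
    warn("non-ACGTN characters treated as N")
  }
  m <- matrix(0, nrow = length(chars), ncol = 4L,
    dimnames = list(NULL, BASES)
  )
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to `N`.
#'
#' @param mat An `L x 4` one-hot matrix (columns A, C, G, T).
#' @return A DNA string of length `L`.
#' @export
one_hot_decode <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  idx <- max.col(mat, ties.method = "first")
  idx[rowSums(mat) == 0] <- 5L
  paste(c(BASES, "N")[idx], collapse = "")
}

#' One-hot tensor for a region, standardized to a fixed window
#'
#' Composes [standardize_window()], [genome_sequence()] and
#' [one_hot_encode()]: the returned matrix is always exactly `width x 4`, with
#' any part of the window falling outside the chromosome encoded as all-zero
#' (N) rows.
#'
#' @param genome An `eei_genome`.
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param width Window size in bp; default 2000.
#' @return A `width x 4` one-hot matrix.
#' @export
region_to_tensor <- function(genome, chrom, start, end, width = 2000L) {
  w <- standardize_window(tibble(chrom = chrom, start = start, end = end), width)
  one_hot_encode(genome_sequence(genome, w$chrom, w$start, w$end))
}
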