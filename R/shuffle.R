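#' Dinucleotide-preserving sequence shuffle
#'
#' Permutes a DNA sequence while exactly preserving its dinucleotide count
#' multiset, using the Eulerian-path construction (random last-edge trees
#' followed by a connectivity check), which samples uniformly from the valid
#' shuffles and keeps the first and last base fixed. `N` (and any non-ACGT)
#' positions are held fixed; the shuffle acts independently on each maximal
#' run of ACGT bases.
#'
#' @param sequence A DNA string.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can seed once for a whole analysis).
#' @return A shuffled DNA string of the same length.
#' @examples
#' dinucleotide_shuffle("ACGTACGTACGT", seed = 1)
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(derive_seed(seed, "dinuc"), dinucleotide_shuffle(sequence)))
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  is_acgt <- chars %in% BASES
  if (!any(is_acgt)) return(paste(chars, collapse = ""))
  # maximal runs of ACGT
  r <- rle(is_acgt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    seg <- chars[starts[i]:ends[i]]
    if (length(seg) >= 3L) {
      chars[starts[i]:ends[i]] <- shuffle_run(seg)
    }
  }
  paste(chars, collapse = "")
}

# Altschul-Erickson shuffle of one ACGT run (character vector)
shuffle_run <- function(seg) {
  n <- length(seg)
  v <- match(seg, BASES)
  from <- v[-n]
  to <- v[-1]
  verts <- sort(unique(v))
  if (length(verts) == 1L) return(seg)
  last_v <- v[n]
  out_edges <- lapply(1:4, function(k) to[from == k])
  # choose a random last edge for every non-terminal vertex such that
  # following last edges always reaches the terminal vertex
  nonterm <- setdiff(verts[vapply(verts, function(k) length(out_edges[[k]]) > 0L, logical(1))], last_v)
  repeat {
    last_edge <- rep(NA_integer_, 4L)
    for (k in nonterm) {
      oe <- out_edges[[k]]
      last_edge[k] <- oe[sample.int(length(oe), 1L)]
    }
    ok <- TRUE
    for (k in nonterm) {
      cur <- k
      for (step in 1:4) {
        cur <- last_edge[cur]
        if (is.na(cur) || cur == last_v) break
      }
      if (is.na(cur) || cur != last_v) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  # order each vertex's edges: random permutation of the rest, last edge last
  ordered <- vector("list", 4L)
  for (k in verts) {
    oe <- out_edges[[k]]
    if (length(oe) == 0L) next
    if (k %in% nonterm) {
      drop_one <- match(last_edge[k], oe)
      rest <- oe[-drop_one]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[k]] <- c(rest, last_edge[k])
    } else {
      ordered[[k]] <- if (length(oe) > 1L) oe[sample.int(length(oe))] else oe
    }
  }
  # walk the Eulerian path from the first base
  res <- integer(n)
  res[1] <- v[1]
  ptr <- rep(1L, 4L)
  cur <- v[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  BASES[res]
}

# shuffle a 0-based half-open [start, end) sub-region of a sequence in place
shuffle_region <- function(sequence, start, end) {
  sub <- substr(sequence, start + 1L, end)
  paste0(
    substr(sequence, 1L, start),
    dinucleotide_shuffle(sub),
    substr(sequence, end + 1L, nchar(sequence))
  )
}
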