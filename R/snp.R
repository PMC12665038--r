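#' In-silico variant effect on predicted interactions
#'
#' For each SNP, builds anchor1 from the `flank` bp immediately upstream of
#' the locus plus the SNP base (standardized to the scorer's window width,
#' keeping surrounding genomic context), pairs it with every partner enhancer
#' (anchor2, same standardization), and scores the pair with the reference
#' and the alternate allele. The per-partner effect is
#' `delta = p_alt - p_ref`; the per-SNP summary is the mean `|delta|` in
#' percentage points.
#'
#' @param scorer A scorer function (see [etnet_scorer()]) or an
#'   `etnet_model`.
#' @param genome An `eei_genome`.
#' @param snps Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   and optionally `snp_id`.
#' @param partners Tibble of partner enhancer regions (`chrom`, `start`,
#'   `end`, `id`).
#' @param flank Upstream flank length in bp (default 150).
#' @param width Model window width; defaults to the model's `seq_len` when a
#'   model is supplied (required for a bare scorer).
#' @return An `eei_snp_delta` object: list with `per_partner` (one row per
#'   SNP x partner: `p_ref`, `p_alt`, `delta`) and `summary` (per SNP:
#'   `mean_abs_delta_pct`).
#' @export
snp_delta <- function(scorer, genome, snps, partners, flank = 150L,
                      width = NULL) {
  if (inherits(scorer, "etnet_model")) {
    width <- scorer$config$seq_len
    scorer <- etnet_scorer(scorer)
  }
  if (is.null(width)) abort("width is required when passing a bare scorer")
  stopifnot(nrow(partners) >= 1L, nrow(snps) >= 1L)
  if (!"snp_id" %in% names(snps)) {
    snps$snp_id <- paste0(snps$chrom, ":", snps$pos, snps$ref, ">", snps$alt)
  }
  partner_seqs <- vapply(seq_len(nrow(partners)), function(j) {
    w <- standardize_window(partners[j, , drop = FALSE], width)
    genome_sequence(genome, w$chrom, w$start, w$end)
  }, character(1))
  rows <- purrr::map(seq_len(nrow(snps)), function(i) {
    chrom <- snps$chrom[i]
    pos <- snps$pos[i]
    ref <- toupper(snps$ref[i])
    alt <- toupper(snps$alt[i])
    if (!alt %in% BASES) {
      abort(paste0("alt allele must be one of A/C/G/T, got ", alt))
    }
    observed <- genome_sequence(genome, chrom, pos - 1L, pos)
    if (observed != ref) {
      abort(paste0(
        "reference mismatch at ", chrom, ":", pos, ": genome has ",
        observed, ", expected ", ref
      ))
    }
    # anchor1: flank bp upstream plus the SNP base, centered in the window
    anchor <- standardize_window(
      tibble(chrom = chrom, start = pos - 1L - flank, end = pos), width
    )
    seq_ref <- genome_sequence(genome, anchor$chrom, anchor$start, anchor$end)
    off <- (pos - 1L) - anchor$start # 0-based offset of the SNP base
    stopifnot(substr(seq_ref, off + 1L, off + 1L) == ref)
    seq_alt <- seq_ref
    substr(seq_alt, off + 1L, off + 1L) <- alt
    np <- length(partner_seqs)
    p_ref <- scorer(rep(seq_ref, np), partner_seqs)
    p_alt <- scorer(rep(seq_alt, np), partner_seqs)
    tibble(
      snp_id = snps$snp_id[i], partner_id = partners$id,
      p_ref = p_ref, p_alt = p_alt, delta = p_alt - p_ref
    )
  })
  per_partner <- bind_rows(rows)
  summary <- per_partner |>
    group_by(.data$snp_id) |>
    summarise(
      n_partners = n(),
      mean_abs_delta_pct = 100 * mean(abs(.data$delta)),
      .groups = "drop"
    )
  structure(
    list(per_partner = per_partner, summary = summary),
    class = "eei_snp_delta"
  )
}

#' @export
print.eei_snp_delta <- function(x, ...) {
  cat("<eei_snp_delta>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.eei_snp_delta <- function(x, ...) x$per_partner

#' @export
glance.eei_snp_delta <- function(x, ...) x$summary
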