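#' Breakpoint-junction microhomology
#'
#' Computes the length of identical sequence shared by the two joined
#' segments at an SV junction, which makes the exact breakpoint placement
#' ambiguous and indexes the double-strand-break repair pathway that formed
#' the junction. The derived junction is `A ++ B`, where `A` is the
#' retained segment of breakend 1 read so that it ends at the junction and
#' `B` is the retained segment of breakend 2 read so that it starts there
#' (reverse complement applied for inversion-type orientation pairs). The
#' homology is `h = h_left + h_right`: `h_right` is the longest prefix of
#' `B` equal to the reference continuation of `A` past the junction, and
#' `h_left` the symmetric quantity upstream. Equivalently, `h + 1` is the
#' number of breakpoint placements that produce an identical derived
#' junction sequence. `N` bases truncate the comparison.
#'
#' @param sv One-row `consensus_sv` or `sv_calls` data frame (or any
#'   list-like with `chrom1`, `pos1`, `orient1`, `chrom2`, `pos2`,
#'   `orient2`).
#' @param genome A `genome_ref` with sequence.
#' @param window Maximum homology tracked per side, bp (default 50).
#' @return List with `homology_len`, `homology_seq` (junction-frame bases),
#'   `h_left`, `h_right`.
#' @export
junction_homology <- function(sv, genome, window = 50) {
  o1 <- sv$orient1; o2 <- sv$orient2
  c1 <- sv$chrom1; p1 <- sv$pos1
  c2 <- sv$chrom2; p2 <- sv$pos2
  k <- window
  # sequences in junction frame: A ends at the junction, B starts there
  if (o1 == "+") {
    a_end <- .genome_seq_raw(genome, c1, p1 - k + 1, p1 + 1)
    a_cont <- .genome_seq_raw(genome, c1, p1 + 1, p1 + 1 + k)
  } else {
    a_end <- .genome_seq_raw(genome, c1, p1 + 1, p1 + 1 + k, strand = "-")
    a_cont <- .genome_seq_raw(genome, c1, p1 - k + 1, p1 + 1, strand = "-")
  }
  if (o2 == "-") {
    b_start <- .genome_seq_raw(genome, c2, p2 + 1, p2 + 1 + k)
    b_prev <- .genome_seq_raw(genome, c2, p2 - k + 1, p2 + 1)
  } else {
    b_start <- .genome_seq_raw(genome, c2, p2 - k + 1, p2 + 1, strand = "-")
    b_prev <- .genome_seq_raw(genome, c2, p2 + 1, p2 + 1 + k, strand = "-")
  }
  nraw <- charToRaw("N")
  lcp <- function(x, y) {
    ok <- x == y & x != nraw
    m <- which(!ok)
    if (length(m) == 0) length(x) else m[1] - 1L
  }
  h_right <- lcp(a_cont, b_start)
  h_left <- lcp(rev(a_end), rev(b_prev))
  hseq <- rawToChar(c(if (h_left > 0) a_end[(k - h_left + 1):k] else raw(0),
                      if (h_right > 0) a_cont[seq_len(h_right)] else raw(0)))
  list(homology_len = h_left + h_right, homology_seq = hseq,
       h_left = h_left, h_right = h_right)
}

#' Classify the repair mechanism from microhomology length
#'
#' Junction homology bins map to the double-strand-break repair pathways
#' that typically produce them: up to 1 bp to non-homologous end joining
#' (NHEJ; blunt 0-bp joins are grouped here unless `blunt_separate`),
#' 2-9 bp to microhomology-mediated end joining (MMEJ), and 10 bp or more
#' to single-strand annealing (SSA).
#'
#' @param h Nonnegative homology length(s), bp.
#' @param nhej_max Upper bound of the NHEJ bin (default 1).
#' @param mmej_max Upper bound of the MMEJ bin (default 9).
#' @param blunt_separate If `TRUE`, h = 0 is labelled `"blunt"` instead of
#'   NHEJ.
#' @return Character vector of labels in
#'   `c("NHEJ", "MMEJ", "SSA", "blunt")`.
#' @export
classify_mechanism <- function(h, nhej_max = 1, mmej_max = 9,
                               blunt_separate = FALSE) {
  stopifnot(all(h >= 0))
  out <- ifelse(h <= nhej_max, "NHEJ", ifelse(h <= mmej_max, "MMEJ", "SSA"))
  if (blunt_separate) out[h == 0] <- "blunt"
  out
}

#' Per-sample repair-mechanism profile and NHEJ:SSA ratio
#'
#' Computes junction homology for every consensus SV, classifies each
#' junction, tabulates mechanism counts per sample, and derives the
#' pseudocounted ratio `(NHEJ + 1) / (SSA + 1)`. When `meta` and
#' `signature_id` are given, the ratio is compared between
#' signature-positive and signature-negative samples with the two-sided
#' rank-sum test.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param genome A `genome_ref` with sequence.
#' @param meta Optional sample metadata (for the signature comparison).
#' @param signature_id Signature to stratify by (default 3).
#' @param cutoff Signature presence cutoff (default 0.06).
#' @param window Homology window (default 50).
#' @return List with `per_sv` (homology and mechanism per SV), `per_sample`
#'   (mechanism counts and `nhej_ssa_ratio`), and `comparison` (rank-sum
#'   result, or `NULL` without metadata).
#' @export
mechanism_profile <- function(consensus, genome, meta = NULL,
                              signature_id = 3, cutoff = 0.06, window = 50) {
  n <- nrow(consensus)
  h <- integer(n); hseq <- character(n)
  cols <- as.list(consensus[, c("chrom1", "pos1", "orient1", "chrom2",
                                "pos2", "orient2")])
  for (i in seq_len(n)) {
    jh <- junction_homology(lapply(cols, `[`, i), genome, window = window)
    h[i] <- jh$homology_len
    hseq[i] <- jh$homology_seq
  }
  per_sv <- data.frame(consensus[, c("sample_id", "chrom1", "pos1", "chrom2",
                                     "pos2", "svtype")],
                       homology_len = h, homology_seq = hseq,
                       mechanism = classify_mechanism(h),
                       stringsAsFactors = FALSE)
  ids <- if (!is.null(meta)) meta$sample_id else unique(per_sv$sample_id)
  tab <- table(factor(per_sv$sample_id, levels = ids),
               factor(per_sv$mechanism, levels = c("NHEJ", "MMEJ", "SSA")))
  per_sample <- data.frame(sample_id = ids, as.data.frame.matrix(tab),
                           stringsAsFactors = FALSE)
  per_sample$nhej_ssa_ratio <- (per_sample$NHEJ + 1) / (per_sample$SSA + 1)
  rownames(per_sample) <- NULL
  comparison <- NULL
  if (!is.null(meta)) {
    pos <- signature_present(meta, signature_id, cutoff)
    r_pos <- per_sample$nhej_ssa_ratio[pos]
    r_neg <- per_sample$nhej_ssa_ratio[!pos]
    if (length(r_pos) > 0 && length(r_neg) > 0)
      comparison <- mann_whitney(r_pos, r_neg)
  }
  list(per_sv = per_sv, per_sample = per_sample, comparison = comparison)
}
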