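#' Per-sample SV class counts
#'
#' Tabulates consensus SVs into DEL/DUP/INV/TRA counts per sample, with the
#' translocation-type count split into intra- and interchromosomal events.
#' Samples listed in `samples` (or in `meta`) but absent from the consensus
#' set are retained as all-zero rows; samples present in the consensus set
#' but missing from `meta` raise an error naming them.
#'
#' @param consensus A `consensus_sv` data frame (see [merge_sample()]).
#' @param samples Optional character vector of sample ids to report.
#' @param meta Optional sample metadata; its `sample_id` column defines the
#'   reported samples and consistency is checked.
#' @return Data frame with columns `sample_id`, `DEL`, `DUP`, `INV`, `TRA`,
#'   `intra_tra`, `inter_tra`, `total`.
#' @export
burden_table <- function(consensus, samples = NULL, meta = NULL) {
  if (!is.null(meta)) {
    missing_meta <- setdiff(unique(consensus$sample_id), meta$sample_id)
    if (length(missing_meta) > 0)
      stop("samples in consensus set but not in metadata: ",
           paste(missing_meta, collapse = ", "))
    samples <- union(samples, meta$sample_id)
  }
  if (is.null(samples)) samples <- unique(consensus$sample_id)
  z <- integer(length(samples))
  out <- data.frame(sample_id = as.character(samples), DEL = z, DUP = z,
                    INV = z, TRA = z, intra_tra = z, inter_tra = z,
                    stringsAsFactors = FALSE)
  if (nrow(consensus) > 0) {
    tab <- table(factor(consensus$sample_id, levels = samples),
                 factor(consensus$svtype, levels = SV_TYPES))
    out[, SV_TYPES] <- as.data.frame.matrix(tab)
    tra <- consensus[consensus$svtype == "TRA", , drop = FALSE]
    intra <- table(factor(tra$sample_id[tra$chrom1 == tra$chrom2],
                          levels = samples))
    out$intra_tra <- as.integer(intra)
    out$inter_tra <- out$TRA - out$intra_tra
  }
  out$total <- out$DEL + out$DUP + out$INV + out$TRA
  out
}

# exact conditional distribution of the group-1 rank sum under ties:
# Streitberg-Roehmel style shift DP over doubled midranks. Returns the
# two-sided p including the observed point in each tail.
.rank_sum_exact_p <- function(scores, take, w_obs) {
  # f[j+1, s+1] = number of size-j subsets with doubled-score sum s
  smax <- sum(sort(scores, decreasing = TRUE)[seq_len(take)])
  f <- matrix(0, nrow = take + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (sc in scores) {
    jmax <- take
    for (j in jmax:1) {
      nz <- which(f[j, ] > 0)
      if (length(nz) > 0) {
        tgt <- nz + sc
        keep <- tgt <= smax + 1
        f[j + 1, tgt[keep]] <- f[j + 1, tgt[keep]] + f[j, nz[keep]]
      }
    }
  }
  dist <- f[take + 1, ]
  total <- sum(dist)
  idx <- which(dist > 0)
  sums <- idx - 1
  lo <- sum(dist[idx[sums <= w_obs]]) / total
  hi <- sum(dist[idx[sums >= w_obs]]) / total
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with an exactness policy suited to small
#' cohorts: the exact conditional distribution (computed by a shift
#' algorithm over doubled midranks, so ties are handled exactly) is used
#' whenever the pooled size is at most `exact_max`; above that, the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest pooled sample size for the exact path
#'   (default 60).
#' @return List with `statistic` (the Mann-Whitney U of group `x`),
#'   `p.value`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_max = 60) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    scores <- as.integer(round(2 * r))
    p <- .rank_sum_exact_p(scores, n1, as.integer(round(2 * w)))
    return(list(statistic = u, p.value = p, method = "exact"))
  }
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = u, p.value = 1, method = "normal"))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Group comparisons of per-sample statistics
#'
#' Runs two-sided pairwise tests between all pairs of groups and (when
#' `fdr = "bh"`) applies Benjamini-Hochberg adjustment across the
#' comparisons of the invocation. Empty groups are skipped and flagged in
#' the `skipped` attribute.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param grouping Factor-like vector of group labels, same length.
#' @param method `"mann-whitney"` (rank-sum, see [mann_whitney()]) or
#'   `"ks"` (Kolmogorov-Smirnov).
#' @param fdr `"bh"` or `"none"`.
#' @return Data frame with `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p`, `p_adj`.
#' @export
compare_groups <- function(values, grouping,
                           method = c("mann-whitney", "ks"),
                           fdr = c("bh", "none")) {
  method <- match.arg(method)
  fdr <- match.arg(fdr)
  grouping <- as.character(grouping)
  keep <- !is.na(values) & !is.na(grouping)
  values <- values[keep]; grouping <- grouping[keep]
  levs <- unique(grouping)
  stopifnot(length(levs) >= 2)
  skipped <- levs[vapply(levs, function(g) sum(grouping == g) == 0, TRUE)]
  levs <- setdiff(levs, skipped)
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    v1 <- values[grouping == g1]; v2 <- values[grouping == g2]
    res <- if (method == "mann-whitney") {
      mann_whitney(v1, v2)
    } else {
      kt <- suppressWarnings(stats::ks.test(v1, v2))
      list(statistic = unname(kt$statistic), p.value = kt$p.value)
    }
    data.frame(group1 = g1, group2 = g2, n1 = length(v1), n2 = length(v2),
               statistic = res$statistic, p = res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (fdr == "bh") stats::p.adjust(out$p, "BH") else out$p
  attr(out, "skipped") <- skipped
  out
}

#' Size spectrum of intrachromosomal SVs
#'
#' Summarizes the empirical log2 size distribution per group and the
#' fraction of events smaller than `small_cutoff`. Interchromosomal events
#' (undefined size) contribute nothing.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param meta Sample metadata containing `sample_id` and the grouping
#'   column.
#' @param group_by Name of the metadata grouping column
#'   (default `"histology"`).
#' @param svtypes SV classes to include (default all four).
#' @param small_cutoff Small-event cutoff in bp (default 10000).
#' @return Data frame per group with `n`, `n_small`, `frac_small`,
#'   `median_size`; attribute `log2_sizes` holds the per-group log2 size
#'   vectors.
#' @export
size_spectrum <- function(consensus, meta, group_by = "histology",
                          svtypes = SV_TYPES, small_cutoff = 10000) {
  stopifnot(group_by %in% names(meta))
  df <- consensus[!is.na(consensus$size) & consensus$svtype %in% svtypes, ,
                  drop = FALSE]
  grp <- meta[[group_by]][match(df$sample_id, meta$sample_id)]
  stopifnot(!anyNA(grp))
  sizes <- split(df$size, grp)
  out <- data.frame(group = names(sizes),
                    n = vapply(sizes, length, 1L),
                    n_small = vapply(sizes, function(s) sum(s < small_cutoff), 1L),
                    stringsAsFactors = FALSE)
  out$frac_small <- ifelse(out$n > 0, out$n_small / out$n, NA_real_)
  out$median_size <- vapply(sizes, function(s)
    if (length(s)) stats::median(s) else NA_real_, 1)
  attr(out, "log2_sizes") <- lapply(sizes, function(s) log2(pmax(s, 1)))
  rownames(out) <- NULL
  out
}
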