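#' Geometric-mean expression score for a gene complex
#'
#' Aggregates the expression of a gene set (e.g. the MRE11-RAD50-NBN
#' double-strand-break sensor complex) into one score per sample as the
#' geometric mean across the genes. With the default `offset = 0` this is
#' the plain geometric mean (a zero value gives score 0, matching the
#' usual geometric-mean helper); `offset = 1` computes the mean on
#' `value + 1` and subtracts 1, which tolerates zeros smoothly and is
#' never negative.
#'
#' @param expr Numeric matrix, genes in rows (unique rownames), samples in
#'   columns; nonnegative.
#' @param genes Character vector of gene names to aggregate.
#' @param offset Nonnegative shift applied inside the log (default 0).
#' @return Named numeric vector of per-sample scores.
#' @export
complex_score <- function(expr, genes, offset = 0) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- expr[genes, , drop = FALSE]
  if (any(sub < 0)) stop("expression values must be nonnegative")
  stopifnot(offset >= 0)
  exp(colMeans(log(sub + offset))) - offset
}

#' Compare two Pearson correlations by Fisher z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Pearson coefficients.
#' @param n1,n2 Sample sizes (each at least 4).
#' @return List with `r1`, `r2`, `n1`, `n2`, `z_stat`, `p`.
#' @export
compare_correlations <- function(r1, r2, n1, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 gives an infinite z-transform")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z_stat = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation comparison between two sample groups
#'
#' Convenience wrapper: computes the groupwise Pearson correlations of `x`
#' and `y` and applies [compare_correlations()].
#'
#' @param x,y Numeric vectors (e.g. complex score and target-gene
#'   expression).
#' @param groups Two-level grouping vector.
#' @return As [compare_correlations()], with group labels attached.
#' @export
compare_group_correlations <- function(x, y, groups) {
  levs <- unique(as.character(groups))
  stopifnot(length(levs) == 2)
  i1 <- groups == levs[1]
  r1 <- stats::cor(x[i1], y[i1])
  r2 <- stats::cor(x[!i1], y[!i1])
  out <- compare_correlations(r1, r2, sum(i1), sum(!i1))
  out$group1 <- levs[1]; out$group2 <- levs[2]
  out
}

#' Downsampling analysis of a small-group correlation
#'
#' Tests whether the (higher) correlation observed in a small group could
#' arise from its size alone: the large group is repeatedly subsampled
#' without replacement to the small group's size, and the reported
#' `downsample_p` is the fraction of draws whose Pearson correlation
#' strictly exceeds the small group's observed one.
#'
#' @param x,y Numeric vectors over all samples.
#' @param small_group Logical or index vector selecting the small group.
#' @param n_draws Number of subsamples (default 10000).
#' @param seed Integer seed.
#' @return List with `r_small`, `r_large`, `n_small`, `n_large`,
#'   `downsample_p`, and the vector of draw correlations in `draws`.
#' @export
downsample_correlation <- function(x, y, small_group, n_draws = 10000,
                                   seed = 1) {
  sel <- rep(FALSE, length(x))
  sel[small_group] <- TRUE
  n_small <- sum(sel); n_large <- sum(!sel)
  stopifnot(n_large > n_small, n_small >= 3, n_draws >= 1)
  r_small <- stats::cor(x[sel], y[sel])
  xl <- x[!sel]; yl <- y[!sel]
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    j <- sample.int(n_large, n_small)
    stats::cor(xl[j], yl[j])
  }, 1)
  list(r_small = r_small, r_large = stats::cor(xl, yl),
       n_small = n_small, n_large = n_large,
       downsample_p = sum(draws > r_small) / n_draws, draws = draws)
}

#' Expression consequences of SVs via per-gene z-scores
#'
#' For each gene, expression is z-scored across samples; SV-bearing samples
#' are reported with their percentile rank (average ranks on ties, scaled
#' to 0-100), and a pooled two-sided rank-sum test compares the aggregated
#' z-scores of SV-bearing versus SV-free observations across genes.
#' Zero-variance genes are skipped and listed.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param sv_status Logical matrix of the same shape: does this sample
#'   carry an SV affecting this gene?
#' @return List with `per_gene` (one row per SV-bearing observation:
#'   gene, sample, z, percentile), `pooled` (rank-sum result or `NULL`),
#'   and `skipped_genes`.
#' @export
sv_expression_percentile <- function(expr, sv_status) {
  stopifnot(identical(dim(expr), dim(sv_status)), ncol(expr) >= 2)
  zs <- vector("list", nrow(expr))
  skipped <- character()
  rows <- list()
  for (g in seq_len(nrow(expr))) {
    v <- as.numeric(expr[g, ])
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      skipped <- c(skipped, rownames(expr)[g])
      next
    }
    z <- (v - mean(v)) / s
    zs[[g]] <- z
    pct <- rank(v, ties.method = "average") / length(v) * 100
    hit <- which(sv_status[g, ])
    if (length(hit) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        gene = rownames(expr)[g] %||% as.character(g),
        sample = colnames(expr)[hit] %||% as.character(hit),
        z = z[hit], percentile = pct[hit], stringsAsFactors = FALSE)
  }
  ok <- which(!vapply(zs, is.null, TRUE))
  z_sv <- unlist(lapply(ok, function(g) zs[[g]][sv_status[g, ]]))
  z_no <- unlist(lapply(ok, function(g) zs[[g]][!sv_status[g, ]]))
  pooled <- if (length(z_sv) > 0 && length(z_no) > 0)
    mann_whitney(z_sv, z_no, exact_max = 0) else NULL
  list(per_gene = if (length(rows)) do.call(rbind, rows) else
         data.frame(gene = character(), sample = character(), z = numeric(),
                    percentile = numeric()),
       pooled = pooled, skipped_genes = skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
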