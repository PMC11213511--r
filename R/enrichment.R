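# conditional noncentral hypergeometric machinery for a 2x2 table
#   (a b / c d), conditioned on both margins: X = a,
#   P(X = x | psi) propto choose(m, x) choose(n, k - x) psi^x
#   with m = a + c, n = b + d, k = a + b, x in [max(0, k - n), min(k, m)]
.nchg_weights <- function(xs, m, n, k, log_psi) {
  lw <- lchoose(m, xs) + lchoose(n, k - xs) + xs * log_psi
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Exact conditional inference for a 2x2 table
#'
#' Computes the conditional maximum-likelihood odds ratio (the value under
#' the noncentral hypergeometric likelihood whose conditional expectation
#' matches the observed count; 0 or +Inf at the support edges), the exact
#' conditional confidence interval obtained by inverting one-sided tail
#' tests at `(1 - conf_level)/2` each, and the two-sided p-value by the
#' probability-ordering method (sum of central-hypergeometric probabilities
#' of tables no more probable than the observed one). This matches the
#' estimator and p-value conventions of standard exact-test
#' implementations, which is what reproduces published odds ratios such as
#' 9.75 for a 5/20-versus-5/155 comparison (the sample cross-product ratio
#' would be 10.0).
#'
#' @param tab A 2x2 matrix/table `rbind(c(a, b), c(c, d))`, rows = group /
#'   non-group, columns = feature-positive / feature-negative; or a length-4
#'   vector `c(a, b, c, d)`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `p`, and the
#'   table counts.
#' @export
fisher_exact <- function(tab, conf_level = 0.95) {
  x <- as.numeric(tab)
  if (length(x) != 4 || any(x < 0) || any(x != floor(x)))
    stop("tab must be four nonnegative integer counts")
  if (is.matrix(tab) || is.table(tab)) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  } else {
    a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  }
  m <- a + cc; n <- b + d; k <- a + b
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0)
    stop("both margins of the 2x2 table must be positive")
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  alpha2 <- (1 - conf_level) / 2

  cond_mean <- function(log_psi) sum(xs * .nchg_weights(xs, m, n, k, log_psi))
  tail_ge <- function(log_psi) {
    w <- .nchg_weights(xs, m, n, k, log_psi)
    sum(w[xs >= a])
  }
  tail_le <- function(log_psi) {
    w <- .nchg_weights(xs, m, n, k, log_psi)
    sum(w[xs <= a])
  }
  root <- function(f, target, increasing = TRUE) {
    g <- function(t) f(t) - target
    loT <- -1; hiT <- 1
    while (g(loT) * g(hiT) > 0 && hiT < 1024) {
      loT <- loT * 2; hiT <- hiT * 2
    }
    exp(stats::uniroot(g, c(loT, hiT), tol = 1e-10)$root)
  }

  odds_ratio <- if (a == lo) 0 else if (a == hi) Inf else root(cond_mean, a)
  ci_low <- if (a == lo) 0 else root(tail_ge, alpha2)
  ci_high <- if (a == hi) Inf else root(tail_le, alpha2)

  p0 <- .nchg_weights(xs, m, n, k, 0)       # central hypergeometric
  p <- sum(p0[p0 <= p0[match(a, xs)] * (1 + 1e-7)])
  list(odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
       p = min(1, p), a = a, b = b, c = cc, d = d,
       conf_level = conf_level)
}

#' Gene-level SV enrichment by group
#'
#' A gene counts as altered in a sample when at least one SV passing the
#' filter overlaps it: interval overlap of the breakend span for
#' intrachromosomal DEL/DUP/INV, a breakend falling inside the gene for
#' translocation-type events. Each gene is then tested per group (group
#' versus rest) with [fisher_exact()] and Benjamini-Hochberg adjustment
#' across all (gene, group) tests of the invocation.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param genes Gene table (`gene_symbol`, `chrom`, `start`, `end`,
#'   `role`).
#' @param meta Sample metadata with `sample_id` and the grouping column.
#' @param group_by Grouping column name (default `"genomic_subtype"`).
#' @param filter `"non-duplication"` (exclude DUP events), `"any"`, or
#'   `"complex-only"` (keep only complex events, see [classify_complex()]).
#' @param ct_regions Chromothripsis regions (needed for
#'   `"complex-only"`).
#' @param conf_level Confidence level for the exact CI.
#' @return Data frame with one row per (gene, group): alteration counts,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `p_adj`. Attribute `altered`
#'   is the gene-by-sample logical matrix.
#' @export
gene_sv_enrichment <- function(consensus, genes, meta,
                               group_by = "genomic_subtype",
                               filter = c("non-duplication", "any",
                                          "complex-only"),
                               ct_regions = NULL, conf_level = 0.95) {
  filter <- match.arg(filter)
  stopifnot(group_by %in% names(meta))
  sv <- consensus
  if (filter == "non-duplication") {
    sv <- sv[sv$svtype != "DUP", , drop = FALSE]
  } else if (filter == "complex-only") {
    sv <- sv[classify_complex(sv, ct_regions), , drop = FALSE]
  }
  ids <- meta$sample_id
  altered <- matrix(FALSE, nrow = nrow(genes), ncol = length(ids),
                    dimnames = list(genes$gene_symbol, ids))
  if (nrow(sv) > 0) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1, genes$end))
    tra <- sv$svtype == "TRA"
    span <- sv[!tra, , drop = FALSE]
    if (nrow(span) > 0) {
      sgr <- GenomicRanges::GRanges(span$chrom1,
                                    IRanges::IRanges(span$pos1 + 1,
                                                     pmax(span$pos2,
                                                          span$pos1 + 1)))
      ov <- GenomicRanges::findOverlaps(ggr, sgr)
      for (h in seq_along(ov)) {
        gi <- S4Vectors::queryHits(ov)[h]
        si <- span$sample_id[S4Vectors::subjectHits(ov)[h]]
        altered[gi, si] <- TRUE
      }
    }
    trx <- sv[tra, , drop = FALSE]
    if (nrow(trx) > 0) {
      bgr <- GenomicRanges::GRanges(c(trx$chrom1, trx$chrom2),
                                    IRanges::IRanges(c(trx$pos1, trx$pos2) + 1,
                                                     width = 1))
      samp2 <- c(trx$sample_id, trx$sample_id)
      ov <- GenomicRanges::findOverlaps(ggr, bgr)
      for (h in seq_along(ov)) {
        gi <- S4Vectors::queryHits(ov)[h]
        altered[gi, samp2[S4Vectors::subjectHits(ov)[h]]] <- TRUE
      }
    }
  }
  grp <- as.character(meta[[group_by]])
  rows <- list()
  for (g in unique(grp[!is.na(grp)])) {
    in_g <- grp == g & !is.na(grp)
    for (gi in seq_len(nrow(genes))) {
      a <- sum(altered[gi, in_g]); b <- sum(in_g) - a
      cc <- sum(altered[gi, !in_g]); d <- sum(!in_g) - cc
      fr <- if ((a + cc) == 0 || (b + d) == 0) NULL else
        fisher_exact(rbind(c(a, b), c(cc, d)), conf_level)
      rows[[length(rows) + 1]] <- data.frame(
        gene_symbol = genes$gene_symbol[gi], group = g,
        altered_in = a, n_group = a + b, altered_rest = cc,
        n_rest = cc + d,
        odds_ratio = if (is.null(fr)) NA_real_ else fr$odds_ratio,
        ci_low = if (is.null(fr)) NA_real_ else fr$ci_low,
        ci_high = if (is.null(fr)) NA_real_ else fr$ci_high,
        p = if (is.null(fr)) NA_real_ else fr$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  attr(out, "altered") <- altered
  out
}

#' Covariate-adjusted SV burden regression
#'
#' For each mutational-signature flag and each count column, fits an
#' ordinary least squares model of `log2(count + 1)` on the signature
#' presence flag plus disease stage, genomic subtype (categorical),
#' coverage, and purity, and reports the two-sided test of the signature
#' coefficient. Samples with missing covariates are dropped (and counted);
#' zero-variance or aliased covariates are dropped with a note.
#'
#' @param counts Data frame with `sample_id` and one column per SV or
#'   mechanism class.
#' @param meta Sample metadata with `sample_id`, signature contribution
#'   columns (`sig<k>`), and the covariates.
#' @param signatures Signature ids to test (default `c(1, 3, 7, 11)`).
#' @param classes Count columns to model (default: all non-id numeric
#'   columns of `counts`).
#' @param covariates Covariate column names present in `meta`.
#' @param cutoff Signature presence cutoff (default 0.06).
#' @return Data frame with one row per (signature, class): `estimate`,
#'   `se`, `t`, `p`, `n`, `dropped`, `note`.
#' @export
burden_regression <- function(counts, meta, signatures = c(1, 3, 7, 11),
                              classes = NULL,
                              covariates = c("stage", "genomic_subtype",
                                             "coverage", "purity"),
                              cutoff = 0.06) {
  if (is.null(classes))
    classes <- setdiff(names(counts)[vapply(counts, is.numeric, TRUE)],
                       "sample_id")
  m <- meta[match(counts$sample_id, meta$sample_id), , drop = FALSE]
  covariates <- intersect(covariates, names(m))
  rows <- list()
  for (sig in signatures) {
    flag <- as.numeric(signature_present(m, sig, cutoff))
    for (cl in classes) {
      y <- log2(counts[[cl]] + 1)
      df <- data.frame(y = y, sig_flag = flag, m[, covariates, drop = FALSE])
      complete <- stats::complete.cases(df)
      dropped <- sum(!complete)
      df <- df[complete, , drop = FALSE]
      note <- ""
      # drop constant covariates (unestimable)
      for (cv in covariates) {
        if (length(unique(df[[cv]])) < 2) {
          df[[cv]] <- NULL
          note <- paste0(note, sprintf("dropped constant covariate %s; ", cv))
        }
      }
      if (length(unique(df$sig_flag)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          signature = sig, class = cl, estimate = NA_real_, se = NA_real_,
          t = NA_real_, p = NA_real_, n = nrow(df), dropped = dropped,
          note = "signature flag constant", stringsAsFactors = FALSE)
        next
      }
      fit <- stats::lm(y ~ ., data = df)
      cf <- summary(fit)$coefficients
      if (any(is.na(stats::coef(fit))))
        note <- paste0(note, "aliased covariate(s) dropped by lm; ")
      if (!"sig_flag" %in% rownames(cf)) {
        est <- se <- tv <- pv <- NA_real_
        note <- paste0(note, "signature coefficient aliased")
      } else {
        est <- cf["sig_flag", 1]; se <- cf["sig_flag", 2]
        tv <- cf["sig_flag", 3]; pv <- cf["sig_flag", 4]
      }
      rows[[length(rows) + 1]] <- data.frame(
        signature = sig, class = cl, estimate = est, se = se, t = tv,
        p = pv, n = nrow(df), dropped = dropped, note = note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
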