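test_that("fisher_exact reproduces published worked examples", {
  # signature 3 in TWT vs non-TWT: 5/20 vs 5/155
  f <- fisher_exact(rbind(c(5, 15), c(5, 150)))
  expect_equal(round(f$odds_ratio, 2), 9.75)
  expect_equal(round(f$ci_low, 2), 2.00)
  expect_equal(f$p, fisher.test(rbind(c(5, 15), c(5, 150)))$p.value,
               tolerance = 1e-9)
  # symmetric table
  f1 <- fisher_exact(c(1, 1, 1, 1))
  expect_equal(f1$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(f1$p, 1)
  # all-in-one-group table: 4/20 vs 0/155
  f2 <- fisher_exact(rbind(c(4, 16), c(0, 155)))
  expect_equal(f2$odds_ratio, Inf)
  expect_equal(round(f2$ci_low, 2), 5.69)
  expect_equal(f2$ci_high, Inf)
  # direct hypergeometric enumeration: observed table is the least
  # probable, so p = P(X = 4) = (20*19*18*17)/(175*174*173*172)
  p_enum <- prod(20:17) / prod(175:172)
  expect_equal(f2$p, p_enum, tolerance = 1e-12)
  expect_equal(signif(f2$p, 2), 1.3e-4)
  # zero margin errors
  expect_error(fisher_exact(c(0, 0, 3, 4)), "margins")
})

test_that("fisher_exact matches stats::fisher.test across random tables", {
  set.seed(14)
  for (trial in 1:60) {
    repeat {
      tab <- matrix(rpois(4, sample(c(2, 5, 15), 1)), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    ft <- fisher.test(tab)
    f <- fisher_exact(tab)
    expect_equal(f$p, ft$p.value, tolerance = 1e-7)
    if (is.finite(f$odds_ratio) && f$odds_ratio > 0)
      expect_equal(f$odds_ratio, unname(ft$estimate), tolerance = 1e-4)
    else
      expect_equal(f$odds_ratio, unname(ft$estimate))
  }
})

test_that("CI bounds invert the one-sided exact tests to 1e-6", {
  tabs <- list(c(5, 15, 5, 150), c(3, 7, 9, 11), c(10, 2, 4, 30),
               c(1, 9, 5, 5))
  for (tt in tabs) {
    a <- tt[1]; b <- tt[2]; cc <- tt[3]; d <- tt[4]
    f <- fisher_exact(tt)
    m <- a + cc; n <- b + d; k <- a + b
    xs <- max(0, k - n):min(k, m)
    tail_p <- function(psi, upper) {
      lw <- lchoose(m, xs) + lchoose(n, k - xs) + xs * log(psi)
      w <- exp(lw - max(lw)); w <- w / sum(w)
      if (upper) sum(w[xs >= a]) else sum(w[xs <= a])
    }
    expect_equal(tail_p(f$ci_low, upper = TRUE), 0.025, tolerance = 1e-6)
    expect_equal(tail_p(f$ci_high, upper = FALSE), 0.025, tolerance = 1e-6)
  }
})

test_that("gene alteration calls respect overlap rules and filters", {
  genes <- data.frame(gene_symbol = c("G1", "G2"), chrom = "c1",
                      start = c(1000, 8000), end = c(2000, 9000),
                      role = c("cancer-gene", "cancer-gene"))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     genomic_subtype = c("TWT", "BRAF", "BRAF"))
  mk <- function(s, p1, p2, type) {
    o <- svmodes:::.orients_for_type(type)
    data.frame(sample_id = s, chrom1 = "c1", pos1 = p1, orient1 = o[1],
               chrom2 = "c1", pos2 = p2, orient2 = o[2], svtype = type,
               size = p2 - p1)
  }
  cons <- rbind(mk("s1", 500, 3000, "DEL"),     # G1 fully inside -> altered
                mk("s2", 900, 2100, "DUP"),     # DUP only
                mk("s3", 7000, 9500, "TRA"))    # TRA span over G2 but
  # TRA counts only via breakends: 7000 and 9500 are both outside G2
  out <- gene_sv_enrichment(cons, genes, meta, filter = "non-duplication")
  alt <- attr(out, "altered")
  expect_true(alt["G1", "s1"])
  expect_false(alt["G1", "s2"])                 # DUP excluded by filter
  expect_false(alt["G2", "s3"])                 # breakends outside gene
  # with a breakend inside the gene the TRA counts
  cons2 <- rbind(cons, mk("s3", 8100, 20000, "TRA"))
  alt2 <- attr(gene_sv_enrichment(cons2, genes, meta, filter = "any"),
               "altered")
  expect_true(alt2["G2", "s3"])
  expect_true(alt2["G1", "s2"])                 # DUP allowed under "any"
})

test_that("group-exclusive alterations yield infinite conditional OR", {
  # TWT-exclusive pattern: 4/20 altered vs 0/155
  meta <- data.frame(sample_id = sprintf("s%03d", 1:175),
                     genomic_subtype = rep(c("TWT", "BRAF"), c(20, 155)))
  genes <- data.frame(gene_symbol = "CBF1", chrom = "c1", start = 1000,
                      end = 2000, role = "tumor-suppressor")
  cons <- do.call(rbind, lapply(sprintf("s%03d", 1:4), function(s)
    data.frame(sample_id = s, chrom1 = "c1", pos1 = 900, orient1 = "+",
               chrom2 = "c1", pos2 = 2100, orient2 = "+", svtype = "INV",
               size = 1200)))
  out <- gene_sv_enrichment(cons, genes, meta, filter = "non-duplication")
  twt <- out[out$group == "TWT", ]
  expect_equal(twt$altered_in, 4)
  expect_equal(twt$altered_rest, 0)
  expect_equal(twt$odds_ratio, Inf)
  expect_equal(round(twt$ci_low, 2), 5.69)
})

test_that("BH adjustment is monotone and stable under repeated calls", {
  set.seed(4)
  p <- runif(20)^2
  adj <- p.adjust(p, "BH")
  # order-preserving: adjusted values are non-decreasing along sorted raw p
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p) && all(adj <= 1))
  # the adjustment itself is deterministic (same input -> same output);
  # note BH is not idempotent under re-application by construction
  expect_identical(p.adjust(p, "BH"), adj)
})

test_that("burden_regression recovers structure and flags degeneracies", {
  sb <- simulate_signature_burden(sim_config(seed = 17), n = 120)
  out <- burden_regression(sb$counts, sb$meta, signatures = c(3, 7))
  expect_equal(nrow(out), 2 * 5)       # 4 classes + total, 2 signatures
  expect_true(all(is.finite(out$p) | !is.na(out$note)))
  # constant covariate dropped with a note
  meta2 <- sb$meta
  meta2$stage <- "III"
  out2 <- burden_regression(sb$counts, meta2, signatures = 3,
                            classes = "DUP")
  expect_match(out2$note, "constant covariate stage")
  expect_true(is.finite(out2$p))
  # constant signature flag flagged, not crashed
  meta3 <- sb$meta
  meta3$sig7 <- 0
  out3 <- burden_regression(sb$counts, meta3, signatures = 7,
                            classes = "DEL")
  expect_match(out3$note, "signature flag constant")
  expect_true(is.na(out3$p))
})
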