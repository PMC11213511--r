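mk_cons <- function(sample, chrom, p1, p2, svtype = "DEL", chrom2 = chrom) {
  o <- svmodes:::.orients_for_type(svtype)
  data.frame(sample_id = sample, chrom1 = chrom, pos1 = p1, orient1 = o[1],
             chrom2 = chrom2, pos2 = p2, orient2 = o[2], svtype = svtype,
             size = ifelse(chrom == chrom2, p2 - p1, NA),
             stringsAsFactors = FALSE)
}

test_that("detect_ba_svs requires full boundary containment and size < 2 Mb", {
  b <- toy_boundaries("c1", starts = 500, width = 100)   # [500, 600)
  cons <- rbind(mk_cons("s1", "c1", 400, 700),     # contains -> BA-SV
                mk_cons("s1", "c1", 550, 700),     # partial overlap -> no
                mk_cons("s1", "c1", 500, 600),     # exact cover -> yes
                mk_cons("s1", "c1", 501, 700),     # misses first base -> no
                mk_cons("s2", "c1", 0, 2e6),       # size exactly 2 Mb -> no
                mk_cons("s2", "c1", 0, 2e6 - 1))   # strictly below -> yes
  ba <- detect_ba_svs(cons, b)
  expect_equal(nrow(ba), 3)
  expect_setequal(ba$sample_id, c("s1", "s2"))
  expect_equal(sum(ba$sample_id == "s1"), 2)
  expect_true(all(ba$boundary_id == "b01"))
})

test_that("containment matches the all-pairs oracle on random fixtures", {
  set.seed(5)
  for (trial in 1:40) {
    nb <- sample(3:12, 1); ns <- sample(5:25, 1)
    bs <- sort(sample.int(5e4, nb)) * 10
    bw <- sample(50:500, nb, replace = TRUE)
    b <- data.frame(chrom = sample(c("c1", "c2"), nb, replace = TRUE),
                    start = bs, end = bs + bw,
                    boundary_id = sprintf("b%02d", seq_len(nb)))
    p1 <- sample.int(5e5, ns)
    sz <- sample.int(3e4, ns) + 10
    cons <- mk_cons("s1", sample(c("c1", "c2"), ns, replace = TRUE),
                    p1, p1 + sz)
    ba <- detect_ba_svs(cons, b)
    spans <- data.frame(chrom = cons$chrom1, start = cons$pos1,
                        end = cons$pos2)
    want <- oracle_containment(spans, b)
    got <- matrix(FALSE, ns, nb)
    if (nrow(ba) > 0) {
      si <- match(ba$sv_key, sprintf("%s:%s:%d-%d:%s", cons$sample_id,
                                     cons$chrom1, as.integer(cons$pos1),
                                     as.integer(cons$pos2), cons$svtype))
      bi <- match(ba$boundary_id, b$boundary_id)
      got[cbind(si, bi)] <- TRUE
    }
    expect_identical(got, want)
  }
})

test_that("functional adjacency and event classes annotate BA-SVs", {
  tads <- data.frame(chrom = "c1", start = c(0, 600), end = c(500, 1200),
                     tad_type = c("repressed", "low-active"))
  b <- toy_boundaries("c1", 500, 100)
  genes <- data.frame(gene_symbol = c("TSG1", "ONC1", "FAR1"),
                      chrom = "c1", start = c(100, 700, 5000),
                      end = c(200, 800, 5100),
                      role = c("tumor-suppressor", "oncogene", "other"))
  cons <- rbind(mk_cons("s1", "c1", 400, 700),
                mk_cons("s1", "c1", 450, 650),    # overlaps the first -> complex
                mk_cons("s2", "c1", 400, 700))
  ct <- data.frame(sample_id = "s2", event_id = "e", chrom = "c1",
                   start = 0, end = 1000)
  ba <- detect_ba_svs(cons, b, tads = tads, genes = genes, ct_regions = ct)
  expect_equal(nrow(ba), 3)
  expect_true(all(ba$tad_left == "repressed"))
  expect_true(all(ba$tad_right == "low-active"))
  expect_true(all(ba$ts_adjacent))
  expect_true(all(ba$onc_adjacent))
  expect_true(all(grepl("ONC1", ba$genes_adjacent)))
  expect_false(any(grepl("FAR1", ba$genes_adjacent)))
  # both s1 events overlap each other -> complex; s2 lies in a
  # chromothripsis region -> complex
  expect_equal(ba$event_class, rep("complex", 3))
  # without chromothripsis annotation, the isolated s2 event keeps its type
  ba2 <- detect_ba_svs(cons, b, tads = tads, genes = genes)
  expect_equal(ba2$event_class[ba2$sample_id == "s2"], "DEL")
  # boundary with no flanking TAD on one side warns and records NA
  tads_half <- tads[1, , drop = FALSE]
  expect_warning(ba3 <- detect_ba_svs(cons, b, tads = tads_half),
                 "without an adjacent TAD")
  expect_true(all(is.na(ba3$tad_right)))
})

test_that("size-preserving permutation: bounds, degenerate cases, seeding", {
  g <- genome_ref(c("c1", "c2"), c(2e5, 1e5))
  b <- toy_boundaries("c1", starts = c(2e4, 6e4, 1e5), width = 200)
  set.seed(11)
  p1 <- sample.int(15e4, 60)
  cons <- mk_cons("s1", "c1", p1, p1 + sample(500:20000, 60, replace = TRUE))
  res <- basv_permutation(cons, b, g, n_perm = 50, seed = 3,
                          return_placements = TRUE)
  pl <- res$placements
  expect_equal(sort(pl$size), sort(cons$size))   # sizes preserved exactly
  expect_true(all(pl$start >= 0))
  lens <- g$chrom_lengths[pl$chrom]
  expect_true(all(pl$end <= lens))               # within chromosome bounds
  res2 <- basv_permutation(cons, b, g, n_perm = 50, seed = 3)
  expect_identical(res$null, res2$null)          # bit-identical under seed
  # zero boundaries: observed 0, all permutations 0, strict ">" gives 0
  res0 <- basv_permutation(cons, b[0, ], g, n_perm = 20, seed = 1)
  expect_equal(res0$observed, 0L)
  expect_true(all(res0$null == 0L))
  expect_equal(res0$p, 0)
  # an SV larger than every chromosome errors
  giant <- mk_cons("s1", "c1", 0, 1.9e6)
  expect_error(basv_permutation(giant, b, g, n_perm = 5, max_size = 2e6),
               "larger than every chromosome")
  # within-chromosome mode keeps the original chromosome
  resw <- basv_permutation(cons, b, g, n_perm = 5, seed = 9,
                           within_chrom = TRUE, return_placements = TRUE)
  expect_true(all(resw$placements$chrom == "c1"))
})

test_that("recurrence, recurrent-boundary fraction, and fragile distances", {
  b <- rbind(toy_boundaries("c1", 500, 100),
             data.frame(chrom = "c1", start = 5e6, end = 5e6 + 100,
                        boundary_id = "b02"))
  cons <- do.call(rbind, c(
    lapply(sprintf("s%d", 1:5), function(s) mk_cons(s, "c1", 400, 700)),
    list(mk_cons("s1", "c1", 5e6 - 100, 5e6 + 200))))
  ba <- detect_ba_svs(cons, b)
  # fragile sites: one overlapping b01, one 650 kb past b02
  fs <- data.frame(site_name = c("FRA_OVER", "FRA11H"),
                   chrom = "c1", start = c(550, 5e6 + 100 + 650000),
                   end = c(650, 5e6 + 100 + 650000 + 1e5))
  ra <- recurrence_and_adjacency(ba, fragile_sites = fs, boundaries = b,
                                 recurrent_min = 5)
  rec <- ra$recurrence
  expect_equal(rec$n_samples[rec$boundary_id == "b01"], 5)
  expect_true(rec$recurrent[rec$boundary_id == "b01"])   # inclusive at 5
  expect_false(rec$recurrent[rec$boundary_id == "b02"])
  # 5 of 6 distinct BA-SVs hit the recurrent boundary
  expect_equal(ra$frac_recurrent, 5 / 6)
  expect_equal(rec$fragile_site_distance[rec$boundary_id == "b01"], 0)
  expect_equal(rec$nearest_fragile_site[rec$boundary_id == "b02"], "FRA11H")
  expect_equal(rec$fragile_site_distance[rec$boundary_id == "b02"], 650000)
})

test_that("deletion/tumor-suppressor and complex/oncogene tables feed the exact test", {
  tads <- data.frame(chrom = "c1", start = c(0, 600), end = c(500, 1200),
                     tad_type = c("repressed", "active"))
  b <- toy_boundaries("c1", 500, 100)
  genes <- data.frame(gene_symbol = "TSG1", chrom = "c1", start = 100,
                      end = 200, role = "tumor-suppressor")
  cons <- do.call(rbind, lapply(1:12, function(i)
    mk_cons(paste0("s", i), "c1", 400, 700,
            svtype = if (i <= 8) "DEL" else "INV")))
  ba <- detect_ba_svs(cons, b, tads = tads, genes = genes)
  ra <- recurrence_and_adjacency(ba, recurrent_min = 5)
  tab <- ra$deletion_ts$table
  expect_equal(as.integer(tab), c(8, 4, 0, 0))  # all ts-adjacent here
  expect_null(ra$deletion_ts$fisher)            # zero margin -> no test
})

test_that("burden/BA-SV correlation behaves on canonical inputs", {
  ids <- sprintf("s%02d", 1:20)
  x <- stats::setNames(as.numeric(1:20), ids)
  grp <- stats::setNames(rep("g", 20), ids)
  out <- basv_burden_correlation(x, x, grp)
  expect_equal(out$r, 1)
  # independence at n = 200: |r| small
  set.seed(2)
  ids2 <- sprintf("t%03d", 1:200)
  a <- stats::setNames(rnorm(200), ids2)
  bb <- stats::setNames(rnorm(200), ids2)
  out2 <- basv_burden_correlation(a, bb, stats::setNames(rep("g", 200), ids2))
  expect_lt(abs(out2$r), 0.2)
  # zero variance flagged
  flat <- stats::setNames(rep(3, 20), ids)
  out3 <- basv_burden_correlation(flat, x, grp)
  expect_true(is.na(out3$r))
  expect_match(out3$note, "zero variance")
  # missing BA-SV samples count as zero
  out4 <- basv_burden_correlation(x, x[1:10], grp)
  expect_equal(out4$n, 20)
})
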