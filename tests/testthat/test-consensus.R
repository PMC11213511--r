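mk_call <- function(caller, chrom1, p1, chrom2, p2, svtype = "DEL",
                    o = NULL, sample = "s1") {
  if (is.null(o)) o <- svmodes:::.orients_for_type(svtype)
  sv_calls(sample_id = sample, caller_id = caller, chrom1 = chrom1,
           pos1 = p1, orient1 = o[1], chrom2 = chrom2, pos2 = p2,
           orient2 = o[2], svtype = svtype)
}

test_that("calls_compatible enforces type, orientation, and the 1 kb rule", {
  a <- mk_call("c1", "chr1", 1000, "chr1", 5000)
  b <- mk_call("c2", "chr1", 1900, "chr1", 5900)
  expect_true(calls_compatible(a, b))            # per-end distances 900
  b2 <- mk_call("c2", "chr1", 2001, "chr1", 5000)
  expect_false(calls_compatible(a, b2))          # 1001 > 1000
  b3 <- mk_call("c2", "chr1", 2000, "chr1", 5000)
  expect_true(calls_compatible(a, b3))           # boundary inclusive
  dup <- mk_call("c2", "chr1", 1000, "chr1", 5000, svtype = "DUP")
  expect_false(calls_compatible(a, dup))         # type must agree
  inv1 <- mk_call("c1", "chr1", 1000, "chr1", 5000, svtype = "INV",
                  o = c("+", "+"))
  inv2 <- mk_call("c2", "chr1", 1000, "chr1", 5000, svtype = "INV",
                  o = c("-", "-"))
  expect_false(calls_compatible(inv1, inv2))     # strand must agree
})

test_that("merge_sample implements the 2-caller / 30 bp consensus contract", {
  trio <- rbind(mk_call("c1", "chr1", 1000, "chr1", 5000),
                mk_call("c2", "chr1", 1000, "chr1", 5000),
                mk_call("c3", "chr1", 1000, "chr1", 5000))
  cons <- merge_sample(trio)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_callers, 3)
  expect_equal(cons$pos1, 1000)                  # identity: unchanged
  expect_equal(cons$pos2, 5000)

  solo <- mk_call("c1", "chr1", 1000, "chr1", 5000)
  expect_equal(nrow(merge_sample(solo)), 0)      # one caller is not enough

  tiny <- rbind(mk_call("c1", "chr1", 1000, "chr1", 1029),
                mk_call("c2", "chr1", 1000, "chr1", 1029))
  expect_equal(nrow(merge_sample(tiny)), 0)      # merged size 29 < 30
  ok30 <- rbind(mk_call("c1", "chr1", 1000, "chr1", 1030),
                mk_call("c2", "chr1", 1000, "chr1", 1030))
  expect_equal(nrow(merge_sample(ok30)), 1)      # inclusive at 30

  expect_equal(nrow(merge_sample(solo[0, ])), 0) # empty input
})

test_that("merged coordinates are per-end lower medians", {
  four <- rbind(mk_call("c1", "chr1", 1000, "chr1", 5000),
                mk_call("c2", "chr1", 1010, "chr1", 5030),
                mk_call("c3", "chr1", 1020, "chr1", 5010),
                mk_call("c4", "chr1", 1030, "chr1", 5020))
  cons <- merge_sample(four)
  expect_equal(cons$pos1, 1010)  # lower median of 1000,1010,1020,1030
  expect_equal(cons$pos2, 5010)  # lower median of 5000,5010,5020,5030
})

test_that("duplicate records are deduplicated with a message", {
  dup2 <- rbind(mk_call("c1", "chr1", 1000, "chr1", 5000),
                mk_call("c1", "chr1", 1000, "chr1", 5000),
                mk_call("c2", "chr1", 1000, "chr1", 5000))
  expect_message(cons <- merge_sample(dup2), "duplicate")
  expect_equal(attr(cons, "n_duplicates"), 1)
  expect_equal(cons$n_members, 2)
})

test_that("clustering matches the brute-force oracle on random fixtures", {
  for (seed in 1:60) {
    n <- sample(5:60, 1)
    calls <- random_call_fixture(n, seed = seed * 13)
    got <- pkg_consensus_signature(merge_sample(calls))
    want <- oracle_consensus_signature(calls)
    expect_identical(got, want)
  }
  # a couple of large fixtures
  for (seed in 1:3) {
    calls <- random_call_fixture(200, seed = 1000 + seed)
    expect_identical(pkg_consensus_signature(merge_sample(calls)),
                     oracle_consensus_signature(calls))
  }
})

test_that("merge output is invariant to input order", {
  calls <- random_call_fixture(80, seed = 99)
  ref <- merge_sample(calls)
  for (seed in 1:5) {
    set.seed(seed)
    shuf <- calls[sample.int(nrow(calls)), ]
    expect_equal(merge_sample(shuf), ref, ignore_attr = TRUE)
  }
})

test_that("increasing max_dist never shrinks supported membership", {
  for (seed in 1:10) {
    calls <- random_call_fixture(60, seed = 500 + seed)
    m1 <- sum(merge_sample(calls, max_dist = 500, min_size = 0)$n_members)
    m2 <- sum(merge_sample(calls, max_dist = 1000, min_size = 0)$n_members)
    m3 <- sum(merge_sample(calls, max_dist = 2000, min_size = 0)$n_members)
    expect_true(m1 <= m2)
    expect_true(m2 <= m3)
  }
})

test_that("strict-clique mode only emits mutually compatible clusters", {
  # chain a-b-c where a and c are 1.2 kb apart: transitive merging joins
  # all three; strict cliques split them
  chain <- rbind(mk_call("c1", "chr1", 1000, "chr1", 5000),
                 mk_call("c2", "chr1", 1600, "chr1", 5000),
                 mk_call("c3", "chr1", 2200, "chr1", 5000))
  trans <- merge_sample(chain)
  expect_equal(trans$n_members, 3)
  strict <- merge_sample(chain, strict_clique = TRUE)
  expect_true(all(strict$n_members <= 2))
})

test_that("merge_cohort tabulates per-sample counts incl. TRA breakdown", {
  calls <- rbind(
    mk_call("c1", "chr1", 1000, "chr1", 9000, "TRA", o = c("+", "-")),
    mk_call("c2", "chr1", 1000, "chr1", 9000, "TRA", o = c("+", "-")),
    mk_call("c1", "chr1", 2000, "chr2", 9000, "TRA", o = c("+", "-")),
    mk_call("c2", "chr1", 2000, "chr2", 9000, "TRA", o = c("+", "-")),
    mk_call("c1", "chr2", 100, "chr2", 700),
    mk_call("c2", "chr2", 100, "chr2", 700))
  out <- merge_cohort(calls, samples = c("s1", "empty"))
  cnt <- out$counts
  s1 <- cnt[cnt$sample_id == "s1", ]
  expect_equal(s1$TRA, 2)
  expect_equal(s1$intra_tra, 1)
  expect_equal(s1$inter_tra, 1)
  expect_equal(s1$DEL, 1)
  expect_equal(s1$total, 3)
  e <- cnt[cnt$sample_id == "empty", ]
  expect_equal(e$total, 0)                       # zero row retained
  expect_equal(nrow(merge_cohort(calls[0, ])$consensus), 0)
})
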