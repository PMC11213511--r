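test_that("the scaffold tiles TADs, boundaries, genes, and fragile sites", {
  cfg <- test_cfg(seed = 41)
  sc <- simulate_genome(cfg)
  # k TADs on a chromosome imply k - 1 internal boundaries
  for (cc in sc$genome$chrom_names) {
    k <- sum(sc$tads$chrom == cc)
    expect_equal(sum(sc$boundaries$chrom == cc), k - 1)
  }
  # all five functional types are represented
  expect_setequal(unique(sc$tads$tad_type),
                  c("heterochromatin", "low", "repressed", "low-active",
                    "active"))
  # boundaries are the gaps between consecutive TADs, non-overlapping
  for (cc in sc$genome$chrom_names) {
    t <- sc$tads[sc$tads$chrom == cc, ]
    b <- sc$boundaries[sc$boundaries$chrom == cc, ]
    expect_equal(b$start, t$end[-nrow(t)])
    expect_equal(b$end, t$start[-1])
    expect_true(all(b$start < b$end))
  }
  # genes lie inside TADs; both cancer roles are present
  expect_true(all(c("oncogene", "tumor-suppressor") %in% sc$genes$role))
  # determinism: same seed, byte-identical
  sc2 <- simulate_genome(cfg)
  expect_identical(sc$tads, sc2$tads)
  expect_identical(sc$genome$seqs, sc2$genome$seqs)
})

test_that("FASTA round trip preserves the genome", {
  cfg <- test_cfg(seed = 42)
  g <- simulate_genome(cfg)$genome
  f <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- genome_from_fasta(f)
  expect_identical(g2$chrom_names, g$chrom_names)
  expect_identical(g2$chrom_lengths, g$chrom_lengths)
  expect_identical(g2$seqs, g$seqs)
  expect_equal(genome_seq(g2, "chr1", 100, 120),
               genome_seq(g, "chr1", 100, 120))
})

test_that("cohort generation is deterministic and internally consistent", {
  cfg <- test_cfg(seed = 43)
  sim <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(test_cfg(seed = 43))
  expect_identical(sim$calls, sim2$calls)
  expect_identical(sim$ledger, sim2$ledger)
  # every emitted call traces to a planted SV or a logged false positive
  expect_true(all(sim$calls$truth_id %in% c(sim$ledger$truth_id, "FP")))
  # chromothripsis ledger flags match the region table's samples
  ct_samples <- unique(sim$ct_regions$sample_id)
  expect_setequal(unique(sim$ledger$sample_id[sim$ledger$in_chromothripsis]),
                  ct_samples)
  # breakends lie within chromosomes
  L <- sim$genome$chrom_lengths
  expect_true(all(sim$ledger$pos1 >= 0 & sim$ledger$pos1 < L[sim$ledger$chrom1]))
  expect_true(all(sim$ledger$pos2 >= 0 & sim$ledger$pos2 < L[sim$ledger$chrom2]))
})

test_that("noiseless limit: consensus merging recovers the ledger exactly", {
  cfg <- test_cfg(seed = 44, jitter_sd = 0, det_p = 1, fp_rate = 0)
  sim <- simulate_cohort(cfg)
  cons <- merge_cohort(sim$calls, samples = sim$meta$sample_id)$consensus
  key <- function(d) sort(paste(d$sample_id, d$chrom1, d$pos1, d$orient1,
                                d$chrom2, d$pos2, d$orient2, d$svtype))
  led <- sim$ledger[is.na(sim$ledger$size) | sim$ledger$size >= 30, ]
  expect_identical(key(cons), key(led))
  expect_true(all(cons$n_callers == length(cfg$callers)))
})

test_that("two-of-three consensus rate matches the binomial closed form", {
  # detection 0.6 with 3 callers: P(>=2 callers) = 3 p^2 (1-p) + p^3
  cfg <- test_cfg(seed = 45, det_p = 0.6, jitter_sd = 0, fp_rate = 0)
  sim <- simulate_cohort(cfg)
  cons <- merge_cohort(sim$calls, samples = sim$meta$sample_id)$consensus
  key <- function(d) paste(d$sample_id, d$chrom1, d$pos1, d$chrom2, d$pos2,
                           d$svtype)
  led <- sim$ledger[is.na(sim$ledger$size) | sim$ledger$size >= 30, ]
  recovered <- mean(key(led) %in% key(cons))
  p_expect <- 3 * 0.6^2 * 0.4 + 0.6^3        # 0.648
  n <- nrow(led)
  expect_lt(abs(recovered - p_expect), 4 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("moderate-noise consensus keeps recall >= 0.9 and precision >= 0.95", {
  cfg <- test_cfg(seed = 46, jitter_sd = 100, det_p = 0.9, fp_rate = 0.05)
  sim <- simulate_cohort(cfg)
  cons <- merge_cohort(sim$calls, samples = sim$meta$sample_id)$consensus
  led <- sim$ledger
  m <- merge(led[, c("sample_id", "svtype", "chrom1", "pos1", "chrom2",
                     "pos2", "truth_id")],
             cons[, c("sample_id", "svtype", "chrom1", "pos1", "chrom2",
                      "pos2")],
             by = c("sample_id", "svtype", "chrom1", "chrom2"),
             suffixes = c(".t", ".c"))
  hit <- abs(m$pos1.t - m$pos1.c) <= 1000 & abs(m$pos2.t - m$pos2.c) <= 1000
  recall <- length(unique(m$truth_id[hit])) / nrow(led)
  # precision: consensus records near a true SV of the same sample/type
  key_c <- paste(m$sample_id, m$svtype, m$pos1.c, m$pos2.c)[hit]
  all_c <- paste(cons$sample_id, cons$svtype, cons$pos1, cons$pos2)
  precision <- mean(all_c %in% key_c)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.95)
})

test_that("expression generator hits configured correlations and determinism", {
  cfg <- sim_config(seed = 47)
  cfg$expr$n_small <- 120; cfg$expr$n_large <- 2000
  cfg$expr$r_small <- 0; cfg$expr$r_large <- 0.82
  ex <- simulate_expression(cfg)
  sc <- complex_score(ex$expr, cfg$expr$genes)
  tg <- ex$expr[cfg$expr$target, ]
  r0 <- cor(sc[ex$groups == "small"], tg[ex$groups == "small"])
  expect_lt(abs(r0), 3 / sqrt(120))            # target correlation 0
  r1 <- cor(sc[ex$groups == "large"], tg[ex$groups == "large"])
  expect_lt(abs(r1 - 0.82), 0.05)
  ex2 <- simulate_expression(cfg)
  expect_identical(ex$expr, ex2$expr)
})

test_that("burden-only generator mirrors the subtype burden model", {
  cfg <- sim_config(seed = 48)
  sb <- simulate_signature_burden(cfg, n = 200)
  expect_equal(nrow(sb$meta), 200)
  expect_true(all(sb$meta$histology == "cutaneous"))
  expect_equal(sb$counts$total,
               rowSums(sb$counts[, c("TRA", "DEL", "INV", "DUP")]))
  # signature-3 samples carry the planted DUP excess on average
  sig3 <- signature_present(sb$meta, 3)
  expect_gte(sum(sig3), 3)   # prevalence model yields carriers at n = 200
  expect_gt(mean(sb$counts$DUP[sig3]), mean(sb$counts$DUP[!sig3]))
})
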