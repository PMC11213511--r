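# shared fixture builders (everything generated in code; no binary files)

# tiny two-chromosome genome with known sequence
tiny_genome <- function(seed = 1, lengths = c(chrA = 5e4, chrB = 3e4)) {
  set.seed(seed)
  seqs <- lapply(lengths, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""))
  genome_ref(names(lengths), lengths, seqs)
}

# random per-sample call fixture for consensus clustering, designed so that
# near-duplicate breakpoints from different callers form nontrivial clusters
random_call_fixture <- function(n, seed, n_callers = 3, chroms = c("c1", "c2"),
                                span = 2e5) {
  set.seed(seed)
  base_n <- max(1, ceiling(n / 2))
  b_chrom <- sample(chroms, base_n, replace = TRUE)
  b_pos <- sample.int(span, base_n)
  b_type <- sample(c("DEL", "DUP", "INV", "TRA"), base_n, replace = TRUE)
  b_size <- sample(50:5e4, base_n, replace = TRUE)
  idx <- sample.int(base_n, n, replace = TRUE)
  caller <- paste0("caller", sample.int(n_callers, n, replace = TRUE))
  jitter1 <- sample(-1500:1500, n, replace = TRUE)
  jitter2 <- sample(-1500:1500, n, replace = TRUE)
  svtype <- b_type[idx]
  ors <- t(vapply(svtype, svmodes:::.orients_for_type, character(2)))
  sv_calls(sample_id = "s1", caller_id = caller,
           chrom1 = b_chrom[idx], pos1 = pmax(0, b_pos[idx] + jitter1),
           orient1 = ors[, 1],
           chrom2 = b_chrom[idx],
           pos2 = pmax(0, b_pos[idx] + b_size[idx] + jitter2),
           orient2 = ors[, 2], svtype = svtype)
}

# small cohort config used across tests: fast but structurally complete
test_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, scale = 0.08,
             chrom_lengths = c(chr1 = 3e6, chr2 = 2.5e6, chr3 = 2e6),
             ...)
}

# boundary/TAD scaffold for containment tests
toy_boundaries <- function(chrom = "c1", starts = c(500), width = 100) {
  data.frame(chrom = chrom, start = starts, end = starts + width,
             boundary_id = sprintf("b%02d", seq_along(starts)),
             stringsAsFactors = FALSE)
}
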