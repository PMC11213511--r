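# independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals they check

# connected components over all compatible pairs (O(n^2) + BFS)
oracle_cluster <- function(calls, max_dist = 1000) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- calls$svtype[i] == calls$svtype[j] &&
        calls$orient1[i] == calls$orient1[j] &&
        calls$orient2[i] == calls$orient2[j] &&
        calls$chrom1[i] == calls$chrom1[j] &&
        calls$chrom2[i] == calls$chrom2[j] &&
        abs(calls$pos1[i] - calls$pos1[j]) <= max_dist &&
        abs(calls$pos2[i] - calls$pos2[j]) <= max_dist
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# consensus records from the oracle clustering, rendered as a sorted
# multiset of record strings for comparison with the package output
oracle_consensus_signature <- function(calls, max_dist = 1000,
                                       min_callers = 2, min_size = 30) {
  key <- paste(calls$caller_id, calls$chrom1, calls$pos1, calls$orient1,
               calls$chrom2, calls$pos2, calls$orient2, calls$svtype)
  calls <- calls[!duplicated(key), , drop = FALSE]
  comp <- oracle_cluster(calls, max_dist)
  sigs <- character(0)
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  for (g in split(seq_len(nrow(calls)), comp)) {
    callers <- unique(calls$caller_id[g])
    if (length(callers) < min_callers) next
    p1 <- lower_median(calls$pos1[g]); p2 <- lower_median(calls$pos2[g])
    if (calls$chrom1[g[1]] == calls$chrom2[g[1]] && (p2 - p1) < min_size)
      next
    sigs <- c(sigs, paste(calls$chrom1[g[1]], p1, calls$orient1[g[1]],
                          calls$chrom2[g[1]], p2, calls$orient2[g[1]],
                          calls$svtype[g[1]], length(callers), length(g)))
  }
  sort(sigs)
}

# the same record rendering for the package's merge output
pkg_consensus_signature <- function(cons) {
  if (nrow(cons) == 0) return(character(0))
  sort(paste(cons$chrom1, cons$pos1, cons$orient1, cons$chrom2, cons$pos2,
             cons$orient2, cons$svtype, cons$n_callers, cons$n_members))
}

# slide-enumeration microhomology oracle: count breakpoint shifts d for
# which the derived junction sequence is identical to the unshifted one
oracle_slide_homology <- function(sv, genome, window = 50) {
  get <- function(chrom, start, end, strand = "+")
    genome_seq(genome, chrom, start, end, strand)
  wlen <- 2 * window + 4
  # fixed absolute anchors: the compared derived sequence covers the same
  # reference region for every shift, so only the junction placement moves
  derived <- function(d) {
    a <- if (sv$orient1 == "+")
      get(sv$chrom1, sv$pos1 - wlen, sv$pos1 + d + 1)
    else get(sv$chrom1, sv$pos1 - d + 1, sv$pos1 + wlen + 1, "-")
    b <- if (sv$orient2 == "-")
      get(sv$chrom2, sv$pos2 + d + 1, sv$pos2 + wlen + 1)
    else get(sv$chrom2, sv$pos2 - wlen, sv$pos2 - d + 1, "-")
    paste0(a, b)
  }
  ref <- derived(0)
  if (grepl("N", ref)) return(NA_integer_)
  hits <- 0L
  for (d in setdiff(-(window):window, 0)) {
    dd <- derived(d)
    if (!grepl("N", dd) && dd == ref) hits <- hits + 1L
  }
  hits
}

# all-pairs boundary containment oracle
oracle_containment <- function(spans, boundaries) {
  out <- matrix(FALSE, nrow(spans), nrow(boundaries))
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(boundaries))) {
      out[i, j] <- spans$chrom[i] == boundaries$chrom[j] &&
        spans$start[i] <= boundaries$start[j] &&
        boundaries$end[j] <= spans$end[i]
    }
  }
  out
}

# exhaustive two-sided Mann-Whitney p by enumeration of all group
# assignments (handles ties); feasible for small pooled sizes only
oracle_mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
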