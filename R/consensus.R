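#' Breakpoint compatibility between two calls
#'
#' Two calls from the same sample are compatible when they agree on SV type
#' and orientation pair, lie on matching chromosomes, and the two
#' corresponding breakends (b1-to-b1 and b2-to-b2 after canonical ordering)
#' are each within `max_dist` base pairs.
#'
#' @param a,b Single-row `sv_calls` data frames (or list-like rows).
#' @param max_dist Maximum per-end breakpoint distance in bp (default 1000).
#' @return `TRUE` or `FALSE`.
#' @export
calls_compatible <- function(a, b, max_dist = 1000) {
  a$svtype == b$svtype &&
    a$orient1 == b$orient1 && a$orient2 == b$orient2 &&
    a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs(a$pos1 - b$pos1) <= max_dist &&
    abs(a$pos2 - b$pos2) <= max_dist
}

# connected components over the compatibility graph of one sample's calls.
# Calls are pre-grouped by (svtype, orientation pair, chromosome pair) and
# sorted by pos1 so only a sliding window of candidates is examined.
.cluster_calls <- function(df, max_dist) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(df$svtype, df$orient1, df$orient2, df$chrom1, df$chrom2)
  for (idx in split(seq_len(n), key)) {
    idx <- idx[order(df$pos1[idx], df$pos2[idx])]
    m <- length(idx)
    if (m < 2) next
    p1 <- df$pos1[idx]; p2 <- df$pos2[idx]
    lo <- 1L
    for (j in 2:m) {
      while (p1[j] - p1[lo] > max_dist) lo <- lo + 1L
      if (lo > j - 1L) next
      for (i in lo:(j - 1L)) {
        if (abs(p2[j] - p2[i]) <= max_dist) {
          ri <- find(idx[i]); rj <- find(idx[j])
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  match(comp, unique(comp))
}

# split one connected component into cliques greedily (deterministic: calls
# visited in canonical sort order, assigned to the first open clique whose
# every member is compatible)
.clique_split <- function(df, members, max_dist) {
  ord <- members[order(df$chrom1[members], df$pos1[members],
                       df$chrom2[members], df$pos2[members],
                       df$caller_id[members])]
  cliques <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(cliques)) {
      ok <- all(vapply(cliques[[k]], function(j)
        calls_compatible(df[i, ], df[j, ], max_dist), TRUE))
      if (ok) {
        cliques[[k]] <- c(cliques[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- i
  }
  cliques
}

# lower median: the floor-median element of a sorted vector
.lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Merge one sample's multi-caller calls into consensus SVs
#'
#' Calls are clustered by connected components of the pairwise
#' compatibility graph (type, orientation, and per-end distance at most
#' `max_dist`); a cluster supported by at least `min_callers` distinct
#' callers is emitted as a consensus record whose breakend positions are
#' the per-end medians of its members (lower median on even counts).
#' Intrachromosomal consensus records shorter than `min_size` are
#' discarded. Duplicate (caller, coordinates, type) records are
#' deduplicated first, and the output is invariant to input order.
#'
#' @param calls `sv_calls` for one sample.
#' @param max_dist Per-end breakpoint distance (bp, default 1000).
#' @param min_callers Minimum number of distinct supporting callers
#'   (default 2).
#' @param min_size Minimum consensus size in bp for intrachromosomal
#'   records (default 30, inclusive).
#' @param strict_clique If `TRUE`, connected components are greedily split
#'   into cliques so that every pair inside an emitted record is
#'   compatible; by default transitive merging is allowed.
#' @return A consensus data frame (class `consensus_sv`) with breakend
#'   columns, `n_callers`, `supporting_callers` (comma-joined), and
#'   `n_members`; attribute `n_duplicates` counts removed duplicates.
#' @export
merge_sample <- function(calls, max_dist = 1000, min_callers = 2,
                         min_size = 30, strict_clique = FALSE) {
  empty <- data.frame(sample_id = character(), chrom1 = character(),
                      pos1 = numeric(), orient1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      orient2 = character(), svtype = character(),
                      size = numeric(), n_callers = integer(),
                      supporting_callers = character(),
                      n_members = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("consensus_sv", class(empty))
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  stopifnot(length(unique(calls$sample_id)) == 1)

  # canonical order makes clustering and merging order-invariant
  df <- calls[order(calls$chrom1, calls$pos1, calls$chrom2, calls$pos2,
                    calls$svtype, calls$orient1, calls$orient2,
                    calls$caller_id), , drop = FALSE]
  rownames(df) <- NULL
  key <- with(df, paste(caller_id, chrom1, pos1, orient1, chrom2, pos2,
                        orient2, svtype))
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message(sprintf("merge_sample: %d duplicate call(s) removed", ndup))
    df <- df[!duplicated(key), , drop = FALSE]
  }

  comp <- .cluster_calls(df, max_dist)
  groups <- split(seq_len(nrow(df)), comp)
  if (strict_clique)
    groups <- unlist(lapply(groups, function(g)
      if (length(g) == 1) list(g) else .clique_split(df, g, max_dist)),
      recursive = FALSE)

  out <- lapply(groups, function(g) {
    callers <- sort(unique(df$caller_id[g]))
    if (length(callers) < min_callers) return(NULL)
    data.frame(sample_id = df$sample_id[g[1]],
               chrom1 = df$chrom1[g[1]], pos1 = .lower_median(df$pos1[g]),
               orient1 = df$orient1[g[1]],
               chrom2 = df$chrom2[g[1]], pos2 = .lower_median(df$pos2[g]),
               orient2 = df$orient2[g[1]], svtype = df$svtype[g[1]],
               n_callers = length(callers),
               supporting_callers = paste(callers, collapse = ","),
               n_members = length(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  intra <- out$chrom1 == out$chrom2
  out$size <- ifelse(intra, out$pos2 - out$pos1, NA_real_)
  out <- out[!(intra & out$size < min_size), , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2, out$svtype),
             c("sample_id", "chrom1", "pos1", "orient1", "chrom2", "pos2",
               "orient2", "svtype", "size", "n_callers",
               "supporting_callers", "n_members")]
  rownames(out) <- NULL
  class(out) <- c("consensus_sv", class(out))
  attr(out, "n_duplicates") <- ndup
  out
}

#' Merge a whole cohort and tabulate per-sample SV class counts
#'
#' @param calls `sv_calls` for any number of samples (QC-passed).
#' @param samples Optional vector of sample ids to include (zero-SV samples
#'   get all-zero count rows).
#' @param ... Passed to [merge_sample()].
#' @return A list with `consensus` (row-bound per-sample consensus sets) and
#'   `counts` (per-sample DEL/DUP/INV/TRA totals with intra-/interchromosomal
#'   TRA breakdown, see [burden_table()]).
#' @export
merge_cohort <- function(calls, samples = NULL, ...) {
  ids <- unique(calls$sample_id)
  if (!is.null(samples)) ids <- union(samples, ids)
  per <- lapply(ids, function(s)
    merge_sample(calls[calls$sample_id == s, , drop = FALSE], ...))
  consensus <- if (length(per) > 0) do.call(rbind, per) else
    merge_sample(calls[0, , drop = FALSE], ...)
  rownames(consensus) <- NULL
  class(consensus) <- unique(c("consensus_sv", class(consensus)))
  list(consensus = consensus,
       counts = burden_table(consensus, samples = ids))
}
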