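#' Flag complex SVs (chromothripsis membership or overlapping footprints)
#'
#' An SV is complex when it lies in a chromothripsis region annotated for
#' its sample, or when its genomic footprint overlaps that of another SV of
#' the same sample (overlapping concomitant DEL, DUP, INV, or TRA events).
#' Footprints are the breakend span for intrachromosomal events and the two
#' 1-bp breakend points for interchromosomal ones.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param ct_regions Optional chromothripsis regions (`sample_id`, `chrom`,
#'   `start`, `end`).
#' @return Logical vector along the rows of `consensus`.
#' @export
classify_complex <- function(consensus, ct_regions = NULL) {
  n <- nrow(consensus)
  complex <- logical(n)
  if (n == 0) return(complex)
  fp <- function(rows) {
    intra <- rows$chrom1 == rows$chrom2
    GenomicRanges::GRanges(
      c(rows$chrom1[intra], rows$chrom1[!intra], rows$chrom2[!intra]),
      IRanges::IRanges(
        c(rows$pos1[intra] + 1, rows$pos1[!intra] + 1, rows$pos2[!intra] + 1),
        c(pmax(rows$pos2[intra], rows$pos1[intra] + 1),
          rows$pos1[!intra] + 1, rows$pos2[!intra] + 1)),
      sv = c(which(intra), which(!intra), which(!intra)))
  }
  for (s in unique(consensus$sample_id)) {
    i <- which(consensus$sample_id == s)
    rows <- consensus[i, , drop = FALSE]
    gr <- fp(rows)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    ov <- S4Vectors::mcols(gr)$sv[S4Vectors::queryHits(hits)] !=
      S4Vectors::mcols(gr)$sv[S4Vectors::subjectHits(hits)]
    touched <- unique(S4Vectors::mcols(gr)$sv[S4Vectors::queryHits(hits)[ov]])
    cx <- logical(length(i))
    cx[touched] <- TRUE
    if (!is.null(ct_regions)) {
      reg <- ct_regions[ct_regions$sample_id == s, , drop = FALSE]
      if (nrow(reg) > 0) {
        rgr <- GenomicRanges::GRanges(reg$chrom,
                                      IRanges::IRanges(reg$start + 1, reg$end))
        inreg <- IRanges::overlapsAny(gr, rgr)
        cx[unique(S4Vectors::mcols(gr)$sv[inreg])] <- TRUE
      }
    }
    complex[i] <- cx
  }
  complex
}

#' Detect boundary-affecting SVs (BA-SVs)
#'
#' A short-range SV (intrachromosomal, size strictly below `max_size`,
#' default 2 Mb) is boundary affecting when its breakend span completely
#' contains a TAD boundary interval. Each (SV, boundary) pair becomes one
#' record, annotated with the functional types of the two TADs flanking the
#' boundary, the cancer-gene content of those TADs, and an event class that
#' collapses chromothripsis-region membership and overlapping concomitant
#' events into `"complex"`.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param boundaries TAD boundary table (`chrom`, `start`, `end`,
#'   `boundary_id`).
#' @param tads Optional TAD table (`chrom`, `start`, `end`, `tad_type`).
#' @param genes Optional gene table (`gene_symbol`, `chrom`, `start`,
#'   `end`, `role`).
#' @param ct_regions Optional chromothripsis regions for the complex class.
#' @param max_size Strict upper size bound in bp (default 2e6).
#' @return Data frame of BA-SV records: `sample_id`, `sv_key` (row key into
#'   the eligible consensus subset), breakend span, `svtype`, `size`,
#'   `boundary_id`, `tad_left`, `tad_right`, `genes_adjacent`,
#'   `ts_adjacent`, `onc_adjacent`, `event_class`.
#' @export
detect_ba_svs <- function(consensus, boundaries, tads = NULL, genes = NULL,
                          ct_regions = NULL, max_size = 2e6) {
  stopifnot(all(c("chrom", "start", "end", "boundary_id") %in% names(boundaries)))
  elig <- which(consensus$chrom1 == consensus$chrom2 &
                  !is.na(consensus$size) & consensus$size < max_size)
  empty <- data.frame(sample_id = character(), sv_key = character(),
                      chrom = character(), pos1 = numeric(), pos2 = numeric(),
                      svtype = character(), size = numeric(),
                      boundary_id = character(), tad_left = character(),
                      tad_right = character(), genes_adjacent = character(),
                      ts_adjacent = logical(), onc_adjacent = logical(),
                      event_class = character(), stringsAsFactors = FALSE)
  if (length(elig) == 0 || nrow(boundaries) == 0) return(empty)
  sv <- consensus[elig, , drop = FALSE]
  sv$sv_key <- sprintf("%s:%s:%d-%d:%s", sv$sample_id, sv$chrom1,
                       as.integer(sv$pos1), as.integer(sv$pos2), sv$svtype)
  complex_all <- classify_complex(consensus, ct_regions)[elig]

  levs <- union(boundaries$chrom, sv$chrom1)
  bgr <- GenomicRanges::GRanges(factor(boundaries$chrom, levels = levs),
                                IRanges::IRanges(boundaries$start + 1,
                                                 boundaries$end))
  span <- GenomicRanges::GRanges(factor(sv$chrom1, levels = levs),
                                 IRanges::IRanges(sv$pos1 + 1,
                                                  pmax(sv$pos2, sv$pos1 + 1)))
  hits <- GenomicRanges::findOverlaps(bgr, span, type = "within")
  if (length(hits) == 0) return(empty)
  bi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  adj <- .boundary_adjacency(boundaries, tads, genes)
  out <- data.frame(sample_id = sv$sample_id[si], sv_key = sv$sv_key[si],
                    chrom = sv$chrom1[si], pos1 = sv$pos1[si],
                    pos2 = sv$pos2[si], svtype = sv$svtype[si],
                    size = sv$size[si],
                    boundary_id = as.character(boundaries$boundary_id[bi]),
                    tad_left = adj$tad_left[bi], tad_right = adj$tad_right[bi],
                    genes_adjacent = adj$genes[bi],
                    ts_adjacent = adj$ts[bi], onc_adjacent = adj$onc[bi],
                    event_class = ifelse(complex_all[si], "complex",
                                         sv$svtype[si]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# functional type of, and gene content in, the TADs flanking each boundary;
# "adjacent" means the TAD edge touches the boundary edge exactly
.boundary_adjacency <- function(boundaries, tads, genes) {
  nb <- nrow(boundaries)
  res <- list(tad_left = rep(NA_character_, nb),
              tad_right = rep(NA_character_, nb),
              genes = rep("", nb), ts = rep(FALSE, nb), onc = rep(FALSE, nb))
  if (is.null(tads)) return(res)
  keyL <- paste(tads$chrom, tads$end)      # TAD ending where boundary starts
  keyR <- paste(tads$chrom, tads$start)    # TAD starting where boundary ends
  iL <- match(paste(boundaries$chrom, boundaries$start), keyL)
  iR <- match(paste(boundaries$chrom, boundaries$end), keyR)
  res$tad_left <- tads$tad_type[iL]
  res$tad_right <- tads$tad_type[iR]
  if (anyNA(iL) || anyNA(iR))
    warning(sprintf("%d boundary side(s) without an adjacent TAD",
                    sum(is.na(iL)) + sum(is.na(iR))))
  if (!is.null(genes) && nrow(genes) > 0) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1, genes$end))
    tgr <- GenomicRanges::GRanges(tads$chrom,
                                  IRanges::IRanges(tads$start + 1, tads$end))
    ov <- GenomicRanges::findOverlaps(tgr, ggr)
    per_tad <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (b in seq_len(nb)) {
      gi <- unique(unlist(per_tad[as.character(c(iL[b], iR[b]))]))
      if (length(gi) == 0) next
      res$genes[b] <- paste(sort(unique(genes$gene_symbol[gi])), collapse = ",")
      res$ts[b] <- any(genes$role[gi] == "tumor-suppressor")
      res$onc[b] <- any(genes$role[gi] == "oncogene")
    }
  }
  res
}

# per-chromosome boundary lookup for fast "does span contain a boundary"
# queries: starts sorted ascending with the suffix minimum of ends
.boundary_index <- function(boundaries, chroms) {
  idx <- lapply(chroms, function(cc) {
    b <- boundaries[boundaries$chrom == cc, , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    o <- order(b$start)
    bs <- b$start[o]; be <- b$end[o]
    sufmin <- rev(cummin(rev(be)))
    list(bs = bs, sufmin = sufmin)
  })
  names(idx) <- chroms
  idx
}

# vectorized containment: span [x, x+s) on chrom index ci contains a boundary?
.spans_contain_boundary <- function(ci, x, s, idx) {
  out <- logical(length(x))
  for (k in unique(ci)) {
    b <- idx[[k]]
    if (is.null(b)) next
    sel <- ci == k
    j <- findInterval(x[sel] - 0.5, b$bs) + 1
    ok <- j <= length(b$bs)
    ok[ok] <- b$sufmin[j[ok]] <= x[sel][ok] + s[sel][ok]
    out[sel] <- ok
  }
  out
}

#' Size-preserving permutation null for BA-SV frequency
#'
#' Each permutation relocates every eligible SV (intrachromosomal, size
#' strictly below `max_size`): the chromosome is drawn with probability
#' proportional to the number of valid placements (`length - size`), and the
#' start uniformly among them. The statistic is the number of SVs whose
#' relocated span fully contains at least one TAD boundary, and the p-value
#' is the proportion of permutations with a strictly higher statistic than
#' observed.
#'
#' @param consensus A `consensus_sv` data frame.
#' @param boundaries TAD boundary table.
#' @param genome A `genome_ref` (lengths only needed).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param max_size Eligibility bound (default 2e6, strict).
#' @param within_chrom If `TRUE`, SVs are reshuffled within their original
#'   chromosome (sensitivity mode).
#' @param smoothed If `TRUE`, report `(x+1)/(n+1)`.
#' @param return_placements If `TRUE`, also return the relocated
#'   coordinates of the final permutation (for auditing that sizes and
#'   chromosome bounds are preserved).
#' @return List with `observed`, `null` (integer vector of permutation
#'   statistics), `p`, and `n_eligible`; plus `placements` when requested.
#' @export
basv_permutation <- function(consensus, boundaries, genome, n_perm = 1000,
                             seed = 1, max_size = 2e6, within_chrom = FALSE,
                             smoothed = FALSE, return_placements = FALSE) {
  stopifnot(inherits(genome, "genome_ref"), n_perm >= 1)
  elig <- consensus[consensus$chrom1 == consensus$chrom2 &
                      !is.na(consensus$size) & consensus$size < max_size, ,
                    drop = FALSE]
  chroms <- genome$chrom_names
  L <- as.numeric(genome$chrom_lengths)
  idx <- .boundary_index(boundaries, chroms)
  n <- nrow(elig)
  obs_ci <- match(elig$chrom1, chroms)
  observed <- sum(.spans_contain_boundary(obs_ci, elig$pos1, elig$size, idx))
  if (n == 0)
    return(list(observed = 0L, null = rep(0L, n_perm),
                p = if (smoothed) 1 / (n_perm + 1) else 0,
                n_eligible = 0L))
  s <- elig$size
  if (any(vapply(s, function(x) all(L <= x), TRUE)))
    stop("an SV is larger than every chromosome")
  # per-SV placement weights per chromosome (fixed across permutations)
  W <- outer(s, L, function(si, Li) pmax(Li - si, 0))
  if (within_chrom) {
    W <- W * 0
    W[cbind(seq_len(n), obs_ci)] <- pmax(L[obs_ci] - s, 0)
  }
  cw <- t(apply(W, 1, cumsum))
  tot <- cw[, ncol(cw)]
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- integer(n_perm)
  placements <- NULL
  for (p_i in seq_len(n_perm)) {
    u <- stats::runif(n) * tot
    ci <- max.col(cw >= u, ties.method = "first")
    x <- floor(stats::runif(n) * (L[ci] - s + 1))
    null[p_i] <- sum(.spans_contain_boundary(ci, x, s, idx))
    if (return_placements && p_i == n_perm)
      placements <- data.frame(chrom = chroms[ci], start = x,
                               end = x + s, size = s,
                               stringsAsFactors = FALSE)
  }
  p <- if (smoothed) (sum(null > observed) + 1) / (n_perm + 1)
       else sum(null > observed) / n_perm
  out <- list(observed = as.integer(observed), null = null, p = p,
              n_eligible = n)
  if (return_placements) out$placements <- placements
  out
}

#' Boundary recurrence and functional-adjacency enrichment
#'
#' Summarizes how often each TAD boundary is hit across samples, the
#' fraction of BA-SVs that strike recurrently altered boundaries, the
#' distance from each boundary to its nearest fragile site, and the two
#' 2x2 enrichments of the boundary analysis: deletion events versus
#' tumor-suppressor-adjacent boundaries, and complex events versus
#' oncogene-adjacent boundaries (both via [fisher_exact()]).
#'
#' @param ba_svs BA-SV records from [detect_ba_svs()].
#' @param fragile_sites Optional fragile-site table (`site_name`, `chrom`,
#'   `start`, `end`).
#' @param boundaries Optional full boundary table (for coordinates of the
#'   fragile-site distance; defaults to coordinates carried in `ba_svs`).
#' @param recurrent_min Minimum number of distinct tumors for a boundary to
#'   count as recurrently altered (default 5, inclusive).
#' @return List with `recurrence` (per-boundary table), `frac_recurrent`
#'   (fraction of distinct BA-SVs hitting a recurrent boundary),
#'   `deletion_ts` and `complex_onc` (each a list of `table` and `fisher`).
#' @export
recurrence_and_adjacency <- function(ba_svs, fragile_sites = NULL,
                                     boundaries = NULL, recurrent_min = 5) {
  if (nrow(ba_svs) == 0)
    return(list(recurrence = data.frame(), frac_recurrent = NA_real_,
                deletion_ts = NULL, complex_onc = NULL))
  rec <- do.call(rbind, lapply(split(ba_svs, ba_svs$boundary_id), function(b) {
    cls <- table(factor(b$event_class,
                        levels = c(SV_TYPES, "complex")))
    data.frame(boundary_id = b$boundary_id[1],
               n_samples = length(unique(b$sample_id)), n_svs = nrow(b),
               DEL = as.integer(cls["DEL"]), DUP = as.integer(cls["DUP"]),
               INV = as.integer(cls["INV"]), TRA = as.integer(cls["TRA"]),
               complex = as.integer(cls["complex"]),
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  rec$recurrent <- rec$n_samples >= recurrent_min

  rec_ids <- rec$boundary_id[rec$recurrent]
  per_sv <- tapply(ba_svs$boundary_id %in% rec_ids, ba_svs$sv_key, any)
  frac_recurrent <- mean(per_sv)

  if (!is.null(fragile_sites) && nrow(fragile_sites) > 0) {
    bcoord <- if (!is.null(boundaries)) boundaries else
      unique(ba_svs[, c("boundary_id", "chrom")])
    if (!is.null(boundaries)) {
      m <- match(rec$boundary_id, boundaries$boundary_id)
      bgr <- GenomicRanges::GRanges(boundaries$chrom[m],
                                    IRanges::IRanges(boundaries$start[m] + 1,
                                                     boundaries$end[m]))
      fgr <- GenomicRanges::GRanges(fragile_sites$chrom,
                                    IRanges::IRanges(fragile_sites$start + 1,
                                                     fragile_sites$end))
      dn <- GenomicRanges::distanceToNearest(bgr, fgr)
      rec$nearest_fragile_site <- NA_character_
      rec$fragile_site_distance <- NA_real_
      qi <- S4Vectors::queryHits(dn)
      rec$nearest_fragile_site[qi] <-
        fragile_sites$site_name[S4Vectors::subjectHits(dn)]
      rec$fragile_site_distance[qi] <- S4Vectors::mcols(dn)$distance
    }
  }

  fish <- function(tab) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    fisher_exact(tab)
  }
  t_del <- table(factor(ba_svs$event_class == "DEL", levels = c(TRUE, FALSE)),
                 factor(ba_svs$ts_adjacent, levels = c(TRUE, FALSE)))
  t_cx <- table(factor(ba_svs$event_class == "complex",
                       levels = c(TRUE, FALSE)),
                factor(ba_svs$onc_adjacent, levels = c(TRUE, FALSE)))
  list(recurrence = rec, frac_recurrent = frac_recurrent,
       deletion_ts = list(table = t_del, fisher = fish(t_del)),
       complex_onc = list(table = t_cx, fisher = fish(t_cx)))
}

#' Correlation between total SV burden and BA-SV burden
#'
#' Pearson correlation (with two-sided t-based p) between per-sample total
#' SV counts and BA-SV counts, per group.
#'
#' @param total_svs Named numeric vector (names = sample ids) of total SV
#'   counts.
#' @param ba_svs Named numeric vector of BA-SV counts (missing samples
#'   count 0).
#' @param grouping Named character vector of group labels.
#' @return Data frame per group: `group`, `n`, `r`, `p`; groups with fewer
#'   than 3 samples or zero variance are flagged `NA` with a reason.
#' @export
basv_burden_correlation <- function(total_svs, ba_svs, grouping) {
  ids <- names(total_svs)
  ba <- ba_svs[ids]
  ba[is.na(ba)] <- 0
  grp <- grouping[ids]
  out <- lapply(unique(grp), function(g) {
    i <- which(grp == g)
    if (length(i) < 3)
      return(data.frame(group = g, n = length(i), r = NA_real_, p = NA_real_,
                        note = "fewer than 3 samples"))
    x <- total_svs[i]; y <- ba[i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(group = g, n = length(i), r = NA_real_, p = NA_real_,
                        note = "zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(group = g, n = length(i), r = unname(ct$estimate),
               p = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
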