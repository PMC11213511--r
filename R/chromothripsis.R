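#' Summarize chromothripsis events
#'
#' Chromothripsis calls are consumed as per-sample region annotations (one
#' row per affected interval, carrying an event id; a single event may span
#' several chromosomes). This summarizes chromosomes per event, flags
#' interchromosomal events (at least 2 chromosomes), and derives per-sample
#' and per-group chromothripsis frequencies.
#'
#' @param regions Data frame with `sample_id`, `event_id`, `chrom`,
#'   `start`, `end`.
#' @param meta Optional sample metadata; defines the sample universe for
#'   frequencies and supplies the grouping column.
#' @param group_by Metadata column for group frequencies
#'   (default `"histology"`).
#' @return List with `events` (per-event chromosome counts and
#'   interchromosomal flag), `samples` (per-sample event count and
#'   has-chromothripsis flag), and `by_group` (frequency per group; `NULL`
#'   without `meta`).
#' @export
event_summary <- function(regions, meta = NULL, group_by = "histology") {
  stopifnot(all(c("sample_id", "event_id", "chrom", "start", "end")
                %in% names(regions)))
  if (nrow(regions) > 0 && any(!nzchar(as.character(regions$event_id))))
    stop("chromothripsis event with empty event id")
  key <- paste(regions$sample_id, regions$event_id, sep = "\r")
  events <- do.call(rbind, lapply(split(regions, key), function(r) {
    data.frame(sample_id = r$sample_id[1], event_id = r$event_id[1],
               n_chroms = length(unique(r$chrom)),
               n_regions = nrow(r), stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(sample_id = character(), event_id = character(),
                         n_chroms = integer(), n_regions = integer())
  events$interchromosomal <- events$n_chroms >= 2
  rownames(events) <- NULL

  ids <- if (!is.null(meta)) meta$sample_id else unique(regions$sample_id)
  n_ev <- table(factor(events$sample_id, levels = ids))
  samples <- data.frame(sample_id = ids, n_events = as.integer(n_ev),
                        stringsAsFactors = FALSE)
  samples$has_chromothripsis <- samples$n_events > 0

  by_group <- NULL
  if (!is.null(meta) && group_by %in% names(meta)) {
    grp <- meta[[group_by]][match(samples$sample_id, meta$sample_id)]
    fr <- tapply(samples$has_chromothripsis, grp, mean)
    by_group <- data.frame(group = names(fr), n = as.integer(table(grp)[names(fr)]),
                           frequency = as.numeric(fr), stringsAsFactors = FALSE)
    rownames(by_group) <- NULL
  }
  list(events = events, samples = samples, by_group = by_group)
}

#' Chromosomal enrichment of chromothripsis-associated breakpoints
#'
#' Tests, per chromosome, whether more chromothripsis-related SV breakpoints
#' are observed than expected from chromosome size alone. Each permutation
#' reassigns every breakpoint to a chromosome with probability proportional
#' to chromosome length (a multinomial draw); the empirical p-value for a
#' chromosome is the fraction of permutations with as many or more
#' breakpoints than observed there.
#'
#' @param breakpoints Data frame with a `chrom` column, one row per
#'   breakpoint (each SV contributes one row per end, so interchromosomal
#'   events count on both chromosomes).
#' @param genome A `genome_ref` (sequence not required).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param smoothed If `TRUE`, report the add-one estimate `(x+1)/(n+1)`
#'   instead of the literal fraction.
#' @param mask Optional data frame (`chrom`, `start`, `end`) of excluded
#'   regions; masked bases are removed from the chromosome weights.
#' @return Data frame per chromosome: `chrom`, `observed`, `expected`,
#'   `p_value`; attribute `null_draws` is the chromosomes-by-permutations
#'   count matrix.
#' @export
chrom_enrichment <- function(breakpoints, genome, n_perm = 1000, seed = 1,
                             smoothed = FALSE, mask = NULL) {
  stopifnot(inherits(genome, "genome_ref"), n_perm >= 1,
            nrow(breakpoints) > 0)
  chroms <- genome$chrom_names
  if (!all(breakpoints$chrom %in% chroms))
    stop("breakpoint chromosome absent from genome: ",
         paste(setdiff(unique(breakpoints$chrom), chroms), collapse = ", "))
  w <- genome$chrom_lengths
  if (!is.null(mask)) {
    masked <- tapply(pmin(mask$end, w[mask$chrom]) - pmax(mask$start, 0),
                     factor(mask$chrom, levels = chroms), sum, default = 0)
    w <- pmax(w - masked, 0)
  }
  obs <- table(factor(breakpoints$chrom, levels = chroms))
  n_bp <- nrow(breakpoints)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- stats::rmultinom(n_perm, size = n_bp, prob = w / sum(w))
  ge <- rowSums(draws >= as.integer(obs))
  p <- if (smoothed) (ge + 1) / (n_perm + 1) else ge / n_perm
  out <- data.frame(chrom = chroms, observed = as.integer(obs),
                    expected = n_bp * as.numeric(w) / sum(w),
                    p_value = as.numeric(p), stringsAsFactors = FALSE)
  attr(out, "null_draws") <- draws
  out
}

# save/restore the RNG state so seeded helpers do not clobber user streams
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fraction of small SVs inside chromothripsis regions
#'
#' An SV counts as inside when both of its breakends fall within
#' chromothripsis regions annotated for its own sample. Fractions are
#' reported per sample and SV class over events smaller than
#' `small_cutoff` (interchromosomal events are excluded with all other
#' undefined-size records).
#'
#' @param consensus A `consensus_sv` data frame.
#' @param regions Chromothripsis region annotations (`sample_id`, `chrom`,
#'   `start`, `end`).
#' @param small_cutoff Size cutoff in bp (default 10000, strict `<`).
#' @param svtypes SV classes to report (default all four).
#' @return Data frame with `sample_id`, `svtype`, `n_small`, `n_inside`,
#'   `frac_inside`.
#' @export
small_sv_in_regions <- function(consensus, regions, small_cutoff = 10000,
                                svtypes = SV_TYPES) {
  sv <- consensus[!is.na(consensus$size) & consensus$size < small_cutoff &
                    consensus$svtype %in% svtypes, , drop = FALSE]
  inside <- logical(nrow(sv))
  if (nrow(sv) > 0 && nrow(regions) > 0) {
    for (s in unique(sv$sample_id)) {
      i <- which(sv$sample_id == s)
      reg <- regions[regions$sample_id == s, , drop = FALSE]
      if (nrow(reg) == 0) next
      gr <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start + 1, reg$end))
      b1 <- GenomicRanges::GRanges(sv$chrom1[i],
                                   IRanges::IRanges(sv$pos1[i] + 1, width = 1))
      b2 <- GenomicRanges::GRanges(sv$chrom2[i],
                                   IRanges::IRanges(sv$pos2[i] + 1, width = 1))
      inside[i] <- IRanges::overlapsAny(b1, gr) & IRanges::overlapsAny(b2, gr)
    }
  }
  grp <- interaction(factor(sv$sample_id), factor(sv$svtype, levels = svtypes),
                     drop = FALSE)
  agg <- data.frame(expand.grid(sample_id = levels(factor(sv$sample_id)),
                                svtype = svtypes, stringsAsFactors = FALSE),
                    stringsAsFactors = FALSE)
  agg$n_small <- as.integer(table(grp))
  agg$n_inside <- as.integer(tapply(inside, grp, sum, default = 0))
  agg$frac_inside <- ifelse(agg$n_small > 0, agg$n_inside / agg$n_small,
                            NA_real_)
  agg[order(agg$sample_id, agg$svtype), ]
}
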