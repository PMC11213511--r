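#' Synthetic-cohort configuration
#'
#' Bundles every parameter of the synthetic melanoma SV cohort: cohort
#' composition (116 acral / 175 cutaneous / 64 mucosal, cutaneous split
#' 81/55/19/20 across BRAF/NRAS/NF1/TWT, at `scale` = 1/4 by default for
#' test speed), the genome scaffold (chromosome lengths, TAD/boundary
#' tiling, genes, fragile sites), per-histology SV burden medians
#' (81/64/23) and class proportions, size mixtures with a small (<10 kb)
#' DEL/INV component for cutaneous tumors, the multi-caller detection
#' model (detection probability, breakpoint jitter, false positives),
#' chromothripsis rates per histology (0.70/0.31/0.25), boundary-planting
#' multiplier, repair-mechanism mixtures and planted microhomology ranges,
#' signature-3 prevalence (enriched in TWT) and its planted burden and
#' mechanism effects, and the expression model. Every quantity with a
#' published counterpart defaults to the published value; the remainder
#' are fixed realistic choices documented in the package vignette.
#'
#' @param seed Integer master seed; the whole cohort is a deterministic
#'   function of the config.
#' @param scale Cohort size multiplier (default 0.25; use 1 for the
#'   full-scale cohort).
#' @param ... Named overrides of any config entry.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, scale = 0.25, ...) {
  hist_n <- pmax(round(c(acral = 116, cutaneous = 175, mucosal = 64) *
                         scale), 2L)
  split <- pmax(round(c(BRAF = 81, NRAS = 55, NF1 = 19, TWT = 20) * scale),
                1L)
  split[1] <- split[1] + (hist_n[["cutaneous"]] - sum(split))
  cfg <- list(
    seed = as.integer(seed),
    histology_n = hist_n,
    cutaneous_split = split,
    chrom_lengths = c(chr1 = 6e6, chr2 = 5e6, chr3 = 4e6, chr4 = 3e6),
    tad_width = 240e3, boundary_width = 10e3,
    genes_per_tad = 2, gene_width = 15e3,
    gene_role_probs = c(oncogene = 0.10, `tumor-suppressor` = 0.10,
                        `cancer-gene` = 0.15, other = 0.65),
    fragile_per_chrom = 2, fragile_width = 100e3,
    burden_median = c(acral = 81, mucosal = 64, cutaneous = 23),
    class_prop = c(TRA = 0.44, DEL = 0.24, INV = 0.17, DUP = 0.15),
    burden_dispersion = 14,
    intra_tra_frac = 0.28,
    small_frac_cutaneous = 0.40, small_frac_other = 0.15,
    small_meanlog = log(3e3), small_sdlog = 0.6,
    large_meanlog = log(6e4), large_sdlog = 1.3,
    min_size = 31, max_size = 2.5e6,
    ba_multiplier = 3,
    callers = c("callerA", "callerB", "callerC"),
    det_p = 0.9, jitter_sd = 100, fp_rate = 0.05,
    ct_frac = c(acral = 0.70, mucosal = 0.31, cutaneous = 0.25),
    ct_chrom_probs = c(0.30, 0.25, 0.25, 0.20),  # chromosomes per event
    ct_region_width = 8e5, ct_sv_per_event = 15,
    mech_probs = c(NHEJ = 0.45, MMEJ = 0.45, SSA = 0.10),
    mech_probs_sig3 = c(NHEJ = 0.65, MMEJ = 0.30, SSA = 0.05),
    h_range = list(NHEJ = 0:1, MMEJ = 2:9, SSA = 10:15),
    homology_window = 50,
    sig3_prev = c(TWT = 5 / 20, other = 5 / 155),
    sig_prev_cutaneous = c(sig1 = 0.5, sig7 = 0.9, sig11 = 0.1),
    sig_prev_other = 0.05,
    sig3_dup_tra_log2 = 0.8,
    nf1_del_mult = 1.5,
    stage_levels = c("II", "III", "IV"),
    purity_shape = c(20, 11), coverage_mean = 57, coverage_sd = 10,
    normal_coverage_mean = 37, normal_coverage_sd = 6, min_coverage = 21,
    expr = list(n_small = 20, n_large = 140, r_small = 0.82,
                r_large = 0.69, base = 1000, sd = 200, gene_noise_sd = 0.05,
                genes = c("MRE11", "NBN", "RAD50"), target = "ATM",
                n_extra_genes = 6))
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the genome scaffold
#'
#' Builds a random nucleotide genome plus the static annotation layers:
#' TADs tiled along each chromosome with one of the five functional type
#' labels, boundaries between consecutive TADs (a chromosome with k TADs
#' has k - 1 boundaries), genes placed inside TADs with cancer roles, and
#' fragile-site intervals.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (a `genome_ref` with sequence), `tads`,
#'   `boundaries`, `genes`, `fragile_sites` (0-based half-open tables).
#' @export
simulate_genome <- function(config) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  L <- config$chrom_lengths
  chroms <- names(L)
  seqs <- lapply(L, function(l)
    charToRaw(paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                    collapse = "")))
  genome <- genome_ref(chroms, L, seqs)

  tw <- config$tad_width; bw <- config$boundary_width
  tad_types <- c("heterochromatin", "low", "repressed", "low-active",
                 "active")
  tads <- list(); bounds <- list(); genes <- list(); frag <- list()
  bid <- 0L
  for (cc in chroms) {
    k <- floor((L[[cc]] + bw) / (tw + bw))
    if (k < 1) stop("chromosome too short for one TAD")
    starts <- (seq_len(k) - 1) * (tw + bw)
    ends <- starts + tw
    ends[k] <- L[[cc]]                       # last TAD absorbs the remainder
    ttype <- sample(tad_types, k, replace = TRUE)
    ttype[seq_len(min(k, 5))] <- sample(tad_types)  # all five represented
    tads[[cc]] <- data.frame(chrom = cc, start = starts, end = ends,
                             tad_type = ttype, stringsAsFactors = FALSE)
    if (k > 1) {
      bs <- ends[-k]; be <- starts[-1]
      bid_new <- bid + seq_along(bs)
      bounds[[cc]] <- data.frame(chrom = cc, start = bs, end = be,
                                 boundary_id = sprintf("b%04d", bid_new),
                                 stringsAsFactors = FALSE)
      bid <- bid + length(bs)
    }
    gl <- list()
    for (t in seq_len(k)) {
      ng <- sample(seq_len(config$genes_per_tad), 1)
      w <- config$gene_width
      avail <- (ends[t] - starts[t]) - w
      if (avail <= 0) next
      gs <- starts[t] + sort(sample.int(avail, ng))
      gl[[t]] <- data.frame(chrom = cc, start = gs, end = gs + w,
                            stringsAsFactors = FALSE)
    }
    genes[[cc]] <- do.call(rbind, gl)
    fs <- sort(sample.int(L[[cc]] - config$fragile_width,
                          config$fragile_per_chrom))
    frag[[cc]] <- data.frame(chrom = cc, start = fs,
                             end = fs + config$fragile_width,
                             stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, tads)
  boundaries <- do.call(rbind, bounds)
  genes <- do.call(rbind, genes)
  genes$gene_symbol <- sprintf("GENE%03d", seq_len(nrow(genes)))
  genes$role <- sample(names(config$gene_role_probs), nrow(genes),
                       replace = TRUE, prob = config$gene_role_probs)
  genes$role[1:2] <- c("oncogene", "tumor-suppressor")  # guarantee both
  frag <- do.call(rbind, frag)
  frag$site_name <- sprintf("FRA%02d", seq_len(nrow(frag)))
  rownames(tads) <- rownames(boundaries) <- rownames(genes) <-
    rownames(frag) <- NULL
  list(genome = genome, tads = tads, boundaries = boundaries,
       genes = genes[, c("gene_symbol", "chrom", "start", "end", "role")],
       fragile_sites = frag[, c("site_name", "chrom", "start", "end")])
}

# analytic probability that a uniformly placed span of `size` fully
# contains at least one boundary (first-order: multiple containment rare
# relative to the boundary spacing)
.null_contain_prob <- function(size, boundaries, chrom_lengths) {
  tot <- sum(pmax(chrom_lengths - size + 1, 0))
  if (tot <= 0) return(0)
  w <- boundaries$end - boundaries$start
  min(1, sum(pmax(size - w + 1, 0)) / tot)
}

# uniform placement of a span (chromosome drawn proportionally to the
# number of valid starts, `pad` bases kept clear of chromosome ends); with
# probability (mult - 1) * q, where q is the analytic null containment
# probability, the span is instead planted to fully contain a random
# feasible boundary -- so the overall boundary-containment rate is about
# mult * q
.place_span <- function(size, mult, bounds, L, pad = 2) {
  q <- .null_contain_prob(size, bounds, L)
  on_b <- stats::runif(1) < min(0.95, max(0, (mult - 1) * q))
  if (on_b && nrow(bounds) > 0) {
    bw_ <- bounds$end - bounds$start
    feas <- which(bw_ <= size & (bounds$end - size) >= 0 &
                    (L[bounds$chrom] >= size + 2 * pad))
    if (length(feas) > 0) {
      b <- if (length(feas) == 1) feas else
        sample(feas, 1, prob = size - bw_[feas] + 1)
      lo <- max(pad, bounds$end[b] - size)
      hi <- min(bounds$start[b], L[[bounds$chrom[b]]] - size - pad)
      if (hi >= lo) {
        x <- floor(stats::runif(1, lo, hi + 1))
        return(list(chrom = bounds$chrom[b], start = x, planted_ba = TRUE))
      }
    }
  }
  wts <- pmax(L - size - 2 * pad, 0)
  if (all(wts == 0)) stop("no chromosome can host a span of this size")
  cc <- sample(names(L), 1, prob = wts)
  x <- floor(stats::runif(1, pad, L[[cc]] - size - pad))
  list(chrom = cc, start = x, planted_ba = FALSE)
}

#' Simulate one set of placed intrachromosomal SVs
#'
#' Lightweight generator used for permutation calibration and power
#' studies: draws `n` intrachromosomal SVs with sizes from the configured
#' mixtures and places them with the configured boundary-planting
#' multiplier (`ba_multiplier = 1` reproduces the uniform null of
#' [basv_permutation()] up to a negligible end-of-chromosome pad).
#'
#' @param config A `sim_config`.
#' @param scaffold Output of [simulate_genome()].
#' @param n Number of SVs.
#' @param histology Histology label controlling the size mixture.
#' @param seed Integer seed.
#' @return A consensus-like data frame with breakend, type, and size
#'   columns plus a `planted_ba` flag.
#' @export
simulate_sv_set <- function(config, scaffold, n, histology = "acral",
                            seed = config$seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- scaffold$genome$chrom_lengths
  bounds <- scaffold$boundaries
  classes <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sz <- .draw_sizes(1, classes[i], histology, config)
    pl <- .place_span(sz, config$ba_multiplier, bounds, L)
    o <- .orients_for_type(classes[i])
    out[[i]] <- data.frame(sample_id = "sim", chrom1 = pl$chrom,
                           pos1 = pl$start, orient1 = o[1],
                           chrom2 = pl$chrom, pos2 = pl$start + sz,
                           orient2 = o[2], svtype = classes[i], size = sz,
                           planted_ba = pl$planted_ba,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# sample metadata for one cohort
.simulate_meta <- function(config) {
  hn <- config$histology_n
  ids <- c(sprintf("ACR%03d", seq_len(hn[["acral"]])),
           sprintf("CUT%03d", seq_len(hn[["cutaneous"]])),
           sprintf("MUC%03d", seq_len(hn[["mucosal"]])))
  hist <- rep(c("acral", "cutaneous", "mucosal"), hn)
  subtype <- rep("not-applicable", length(ids))
  subtype[hist == "cutaneous"] <- rep(names(config$cutaneous_split),
                                      config$cutaneous_split)
  meta <- data.frame(sample_id = ids, histology = hist,
                     genomic_subtype = subtype,
                     purity = stats::rbeta(length(ids),
                                           config$purity_shape[1],
                                           config$purity_shape[2]),
                     ploidy = round(stats::runif(length(ids), 1.8, 3.6), 1),
                     coverage = pmax(config$min_coverage,
                                     stats::rnorm(length(ids),
                                                  config$coverage_mean,
                                                  config$coverage_sd)),
                     normal_coverage = pmax(config$min_coverage,
                                            stats::rnorm(length(ids),
                                                         config$normal_coverage_mean,
                                                         config$normal_coverage_sd)),
                     stage = sample(config$stage_levels, length(ids),
                                    replace = TRUE),
                     stringsAsFactors = FALSE)
  cut <- meta$histology == "cutaneous"
  p3 <- ifelse(meta$genomic_subtype == "TWT", config$sig3_prev[["TWT"]],
               config$sig3_prev[["other"]])
  draw_contrib <- function(present) {
    ifelse(present, stats::runif(length(present), 0.06, 0.5),
           stats::runif(length(present), 0, 0.059))
  }
  meta$sig3 <- draw_contrib(cut & stats::runif(nrow(meta)) < p3)
  for (sg in names(config$sig_prev_cutaneous)) {
    pr <- ifelse(cut, config$sig_prev_cutaneous[[sg]],
                 config$sig_prev_other)
    meta[[sg]] <- draw_contrib(stats::runif(nrow(meta)) < pr)
  }
  meta
}

# expected per-class SV count for one sample (shared by the full cohort
# generator and the fast burden-only generator)
.burden_mu <- function(meta_row, config) {
  mu <- config$burden_median[[meta_row$histology]] * config$class_prop
  if (meta_row$genomic_subtype == "NF1")
    mu[["DEL"]] <- mu[["DEL"]] * config$nf1_del_mult
  if (meta_row$histology == "cutaneous" && meta_row$sig3 >= 0.06) {
    mu[["DUP"]] <- mu[["DUP"]] * 2^config$sig3_dup_tra_log2
    mu[["TRA"]] <- mu[["TRA"]] * 2^config$sig3_dup_tra_log2
  }
  mu
}

# draw one intrachromosomal size from the class/histology mixture
.draw_sizes <- function(n, svclass, histology, config) {
  small_p <- if (histology == "cutaneous" && svclass %in% c("DEL", "INV"))
    config$small_frac_cutaneous else config$small_frac_other
  small <- stats::runif(n) < small_p
  s <- numeric(n)
  s[small] <- stats::rlnorm(sum(small), config$small_meanlog,
                            config$small_sdlog)
  s[!small] <- stats::rlnorm(sum(!small), config$large_meanlog,
                             config$large_sdlog)
  s[small] <- pmin(s[small], 9999)             # the <10 kb component
  round(pmin(pmax(s, config$min_size), config$max_size))
}

#' Simulate a full multi-caller cohort with truth ledger
#'
#' Generates, per sample: true SVs (class counts from the subtype burden
#' model, sizes from the histology mixtures, placements with a configurable
#' excess on TAD boundaries), chromothripsis events (clustered SVs inside
#' annotated regions, possibly spanning several chromosomes), and planted
#' breakpoint microhomologies realized physically in the genome sequence
#' (flanking bases are copied across the junction so the repair module is
#' tested against sequence ground truth). Each true SV is then emitted by
#' each caller independently with the configured detection probability and
#' breakpoint jitter, plus per-caller false positives. The truth ledger
#' records every planted SV and every false positive.
#'
#' @param config A `sim_config`.
#' @param scaffold Output of [simulate_genome()] (built from `config` if
#'   omitted). Its genome is modified by homology planting; use the genome
#'   returned here for downstream sequence analysis.
#' @return List with `calls` (multi-caller `sv_calls` with a `truth_id`
#'   column), `meta`, `ct_regions`, `ledger`, `genome`, `scaffold`,
#'   `config`.
#' @export
simulate_cohort <- function(config, scaffold = NULL) {
  if (is.null(scaffold)) scaffold <- simulate_genome(config)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  genome <- scaffold$genome
  L <- genome$chrom_lengths
  chroms <- genome$chrom_names
  w <- config$homology_window
  meta <- .simulate_meta(config)
  bounds <- scaffold$boundaries

  blocked <- new.env(hash = TRUE, parent = emptyenv())
  block_keys <- function(chrom, pos)
    paste0(chrom, ":", seq(floor((pos - w - 2) / 256),
                           floor((pos + w + 2) / 256)))
  flanks_free <- function(chrom1, p1, chrom2, p2) {
    ks <- c(block_keys(chrom1, p1), block_keys(chrom2, p2))
    !any(vapply(ks, function(k) !is.null(blocked[[k]]), TRUE))
  }
  block_flanks <- function(chrom1, p1, chrom2, p2) {
    for (k in c(block_keys(chrom1, p1), block_keys(chrom2, p2)))
      blocked[[k]] <- TRUE
  }

  base_at <- function(chrom, pos) rawToChar(genome$seqs[[chrom]][pos + 1])
  comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  # A-side continuation base j (1-based past the junction) in junction frame
  a_cont_base <- function(c1, p1, o1, j) {
    if (o1 == "+") base_at(c1, p1 + j) else comp1(base_at(c1, p1 - j + 1))
  }
  # write the B-side base j so that it equals `val` in junction frame
  set_b_base <- function(c2, p2, o2, j, val) {
    if (o2 == "-") genome$seqs[[c2]][p2 + j + 1] <<- charToRaw(val)
    else genome$seqs[[c2]][p2 - j + 2] <<- charToRaw(comp1(val))
  }
  b_prev_base <- function(c2, p2, o2) {          # base just before B starts
    if (o2 == "-") base_at(c2, p2) else comp1(base_at(c2, p2 + 1))
  }
  set_b_prev <- function(c2, p2, o2, val) {
    if (o2 == "-") genome$seqs[[c2]][p2 + 1] <<- charToRaw(val)
    else genome$seqs[[c2]][p2 + 2] <<- charToRaw(comp1(val))
  }
  a_end_base <- function(c1, p1, o1) {
    if (o1 == "+") base_at(c1, p1) else comp1(base_at(c1, p1 + 1))
  }

  plant <- function(c1, p1, o1, c2, p2, o2, h) {
    if (c1 == c2 && abs(p2 - p1) < 2 * (h + 2)) return(FALSE)
    if (!flanks_free(c1, p1, c2, p2)) return(FALSE)
    if (h > 0)
      for (j in seq_len(h)) set_b_base(c2, p2, o2, j, a_cont_base(c1, p1, o1, j))
    nxt <- a_cont_base(c1, p1, o1, h + 1)
    set_b_base(c2, p2, o2, h + 1, other_base(nxt))
    if (b_prev_base(c2, p2, o2) == a_end_base(c1, p1, o1))
      set_b_prev(c2, p2, o2, other_base(a_end_base(c1, p1, o1)))
    block_flanks(c1, p1, c2, p2)
    TRUE
  }

  pick_pos <- function(chrom, lo_pad = w + 2) {
    floor(stats::runif(1, lo_pad, L[[chrom]] - lo_pad))
  }
  pick_chrom <- function(n = 1, exclude_size = 0)
    sample(chroms, n, prob = pmax(L - exclude_size, 0),
           replace = n > length(chroms))

  place_span <- function(size, mult)
    .place_span(size, mult, bounds, L, pad = w + 2)

  truth <- list(); regions <- list()
  for (si in seq_len(nrow(meta))) {
    mrow <- meta[si, ]
    sid <- mrow$sample_id
    sig3 <- mrow$histology == "cutaneous" && mrow$sig3 >= 0.06
    mech_p <- if (sig3) config$mech_probs_sig3 else config$mech_probs
    mu <- .burden_mu(mrow, config)
    counts <- stats::rnbinom(4, mu = mu, size = config$burden_dispersion)
    names(counts) <- names(mu)
    rows <- list()
    add_sv <- function(c1, p1, o1, c2, p2, o2, svtype, in_ct) {
      mech <- sample(names(mech_p), 1, prob = mech_p)
      h <- sample(config$h_range[[mech]], 1)
      ok <- plant(c1, p1, o1, c2, p2, o2, h)
      rows[[length(rows) + 1]] <<- data.frame(
        sample_id = sid, chrom1 = c1, pos1 = p1, orient1 = o1,
        chrom2 = c2, pos2 = p2, orient2 = o2, svtype = svtype,
        mechanism = mech, homology_len = ifelse(ok, h, NA_integer_),
        homology_planted = ok, in_chromothripsis = in_ct,
        planted_ba = FALSE, stringsAsFactors = FALSE)
    }
    for (cl in names(counts)) {
      n_cl <- counts[[cl]]
      if (n_cl == 0) next
      if (cl == "TRA") {
        for (i in seq_len(n_cl)) {
          if (stats::runif(1) < config$intra_tra_frac) {
            sz <- .draw_sizes(1, "TRA", mrow$histology, config)
            pl <- place_span(sz, config$ba_multiplier)
            o <- sample(c("+", "-"), 2, replace = TRUE)
            add_sv(pl$chrom, pl$start, o[1], pl$chrom, pl$start + sz, o[2],
                   "TRA", FALSE)
            rows[[length(rows)]]$planted_ba <- pl$planted_ba
          } else {
            cs <- sample(chroms, 2, prob = L)
            o <- sample(c("+", "-"), 2, replace = TRUE)
            add_sv(cs[1], pick_pos(cs[1]), o[1], cs[2], pick_pos(cs[2]),
                   o[2], "TRA", FALSE)
          }
        }
      } else {
        szs <- .draw_sizes(n_cl, cl, mrow$histology, config)
        for (i in seq_len(n_cl)) {
          pl <- place_span(szs[i], config$ba_multiplier)
          o <- if (cl == "INV") {
            if (stats::runif(1) < 0.5) c("+", "+") else c("-", "-")
          } else .orients_for_type(cl)
          add_sv(pl$chrom, pl$start, o[1], pl$chrom, pl$start + szs[i],
                 o[2], cl, FALSE)
          rows[[length(rows)]]$planted_ba <- pl$planted_ba
        }
      }
    }
    # chromothripsis: clustered SVs inside annotated regions
    if (stats::runif(1) < config$ct_frac[[mrow$histology]]) {
      ev_id <- paste0(sid, "_ct1")
      k <- sample(seq_along(config$ct_chrom_probs), 1,
                  prob = config$ct_chrom_probs)
      ev_chroms <- sample(chroms, min(k, length(chroms)), prob = L)
      reg <- lapply(ev_chroms, function(cc) {
        rw <- min(config$ct_region_width, L[[cc]] / 2)
        st <- floor(stats::runif(1, w + 2, L[[cc]] - rw - w - 2))
        data.frame(sample_id = sid, event_id = ev_id, chrom = cc,
                   start = st, end = st + rw, stringsAsFactors = FALSE)
      })
      reg <- do.call(rbind, reg)
      regions[[length(regions) + 1]] <- reg
      for (i in seq_len(config$ct_sv_per_event)) {
        if (nrow(reg) >= 2 && stats::runif(1) < 0.4) {
          rr <- reg[sample.int(nrow(reg), 2), ]
          o <- sample(c("+", "-"), 2, replace = TRUE)
          add_sv(rr$chrom[1],
                 floor(stats::runif(1, rr$start[1] + w, rr$end[1] - w)), o[1],
                 rr$chrom[2],
                 floor(stats::runif(1, rr$start[2] + w, rr$end[2] - w)), o[2],
                 "TRA", TRUE)
        } else {
          rr <- reg[sample.int(nrow(reg), 1), ]
          cl <- sample(c("DEL", "INV", "DUP"), 1)
          sz <- min(.draw_sizes(1, cl, mrow$histology, config),
                    (rr$end - rr$start) / 2)
          st <- floor(stats::runif(1, rr$start + w,
                                   rr$end - sz - w))
          o <- if (cl == "INV") c("+", "+") else .orients_for_type(cl)
          add_sv(rr$chrom, st, o[1], rr$chrom, st + sz, o[2], cl, TRUE)
        }
      }
    }
    truth[[si]] <- do.call(rbind, rows)
  }
  ledger <- do.call(rbind, truth)
  ledger <- canonicalize_breakends(ledger, chrom_order = chroms)
  ledger$truth_id <- sprintf("sv%06d", seq_len(nrow(ledger)))
  ct_regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(sample_id = character(), event_id = character(),
               chrom = character(), start = numeric(), end = numeric())

  # caller emission: independent detection + breakend jitter + false calls
  emitted <- list()
  for (k in config$callers) {
    det <- stats::runif(nrow(ledger)) < config$det_p
    sub <- ledger[det, , drop = FALSE]
    if (nrow(sub) > 0) {
      jit <- function(chrom, pos) {
        p <- pos + round(stats::rnorm(length(pos), 0, config$jitter_sd))
        bad <- p < 1 | p > L[chrom] - 2
        while (any(bad)) {
          p[bad] <- pos[bad] + round(stats::rnorm(sum(bad), 0,
                                                  config$jitter_sd))
          bad <- p < 1 | p > L[chrom] - 2
        }
        p
      }
      emitted[[length(emitted) + 1]] <- data.frame(
        sample_id = sub$sample_id, caller_id = k,
        chrom1 = sub$chrom1, pos1 = jit(sub$chrom1, sub$pos1),
        orient1 = sub$orient1, chrom2 = sub$chrom2,
        pos2 = jit(sub$chrom2, sub$pos2), orient2 = sub$orient2,
        svtype = sub$svtype, truth_id = sub$truth_id,
        stringsAsFactors = FALSE)
    }
    n_fp <- stats::rpois(1, config$fp_rate * nrow(ledger))
    if (n_fp > 0) {
      fp_samp <- sample(meta$sample_id, n_fp, replace = TRUE)
      fp <- lapply(seq_len(n_fp), function(i) {
        cl <- sample(SV_TYPES, 1)
        if (cl == "TRA") {
          cs <- sample(chroms, 2, prob = L)
          data.frame(sample_id = fp_samp[i], caller_id = k,
                     chrom1 = cs[1], pos1 = pick_pos(cs[1]), orient1 = "+",
                     chrom2 = cs[2], pos2 = pick_pos(cs[2]), orient2 = "-",
                     svtype = "TRA", truth_id = "FP",
                     stringsAsFactors = FALSE)
        } else {
          sz <- .draw_sizes(1, cl, "acral", config)
          cc <- pick_chrom(1, exclude_size = sz + 2 * (w + 2))
          st <- floor(stats::runif(1, w + 2, L[[cc]] - sz - w - 2))
          o <- .orients_for_type(cl)
          data.frame(sample_id = fp_samp[i], caller_id = k,
                     chrom1 = cc, pos1 = st, orient1 = o[1],
                     chrom2 = cc, pos2 = st + sz, orient2 = o[2],
                     svtype = cl, truth_id = "FP", stringsAsFactors = FALSE)
        }
      })
      emitted[[length(emitted) + 1]] <- do.call(rbind, fp)
    }
  }
  calls <- canonicalize_breakends(do.call(rbind, emitted),
                                  chrom_order = chroms)
  calls <- calls[order(calls$sample_id, calls$caller_id, calls$chrom1,
                       calls$pos1), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, meta = meta, ct_regions = ct_regions,
       ledger = ledger, genome = genome, scaffold = scaffold,
       config = config)
}

#' Fast burden-only cohort (no SV placement)
#'
#' Draws sample metadata and per-class SV counts from the same burden
#' model as [simulate_cohort()], without placing SVs on the genome. Used
#' for regression calibration and power studies where only counts matter.
#'
#' @param config A `sim_config`.
#' @param n Number of cutaneous samples (default: the config's cutaneous
#'   count).
#' @param sig3_effect_log2 Planted signature-3 DUP/TRA effect (overrides
#'   the config; 0 = null cohort).
#' @return List with `meta` and `counts` (per-class + `total`).
#' @export
simulate_signature_burden <- function(config, n = NULL,
                                      sig3_effect_log2 = NULL) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 3L)
  if (!is.null(sig3_effect_log2)) config$sig3_dup_tra_log2 <- sig3_effect_log2
  if (!is.null(n)) {
    config$histology_n <- c(acral = 0L, cutaneous = as.integer(n),
                            mucosal = 0L)
    sp <- pmax(1L, as.integer(round(c(81, 55, 19, 20) / 175 * n)))
    sp[1] <- sp[1] + n - sum(sp)
    config$cutaneous_split <- stats::setNames(sp, c("BRAF", "NRAS", "NF1",
                                                    "TWT"))
  }
  meta <- .simulate_meta(config)
  counts <- t(vapply(seq_len(nrow(meta)), function(i) {
    mu <- .burden_mu(meta[i, ], config)
    stats::rnbinom(4, mu = mu, size = config$burden_dispersion)
  }, numeric(4)))
  colnames(counts) <- names(config$class_prop)
  counts <- data.frame(sample_id = meta$sample_id, counts,
                       stringsAsFactors = FALSE)
  counts$total <- rowSums(counts[, names(config$class_prop)])
  list(meta = meta, counts = counts)
}

#' Simulate an expression matrix with group-wise MRN-ATM coupling
#'
#' Latent bivariate-normal scores with the configured per-group Pearson
#' correlation are mapped linearly to positive expression; the complex
#' genes share the latent score up to small multiplicative noise, so the
#' geometric-mean complex score preserves the planted correlation with the
#' target gene.
#'
#' @param config A `sim_config` (see its `expr` entry).
#' @return List with `expr` (genes x samples matrix), `groups` (named
#'   vector: `"small"`/`"large"`), and the planted correlations.
#' @export
simulate_expression <- function(config) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  e <- config$expr
  n <- e$n_small + e$n_large
  grp <- rep(c("small", "large"), c(e$n_small, e$n_large))
  r <- ifelse(grp == "small", e$r_small, e$r_large)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  s_lat <- z1
  t_lat <- r * z1 + sqrt(1 - r^2) * z2
  base_s <- e$base + e$sd * s_lat
  target <- pmax(0, e$base + e$sd * t_lat)
  mat <- sapply(e$genes, function(g)
    pmax(0, base_s * exp(stats::rnorm(n, 0, e$gene_noise_sd))))
  extra <- sapply(seq_len(e$n_extra_genes), function(i)
    pmax(0, e$base * exp(stats::rnorm(n, 0, 0.3))))
  colnames(extra) <- sprintf("BG%02d", seq_len(e$n_extra_genes))
  expr <- t(cbind(mat, target = target, extra))
  rownames(expr) <- c(e$genes, e$target, colnames(extra))
  colnames(expr) <- sprintf("S%03d", seq_len(n))
  names(grp) <- colnames(expr)
  list(expr = expr, groups = grp, r_small = e$r_small, r_large = e$r_large)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits the genome FASTA, one BEDPE per (sample, caller), and versioned
#' TSVs for metadata, chromothripsis regions, annotation layers, and the
#' truth ledger.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  for (s in unique(sim$calls$sample_id)) {
    for (k in unique(sim$calls$caller_id)) {
      sub <- sim$calls[sim$calls$sample_id == s & sim$calls$caller_id == k, ]
      if (nrow(sub) > 0)
        write_bedpe(sub, file.path(dir, sprintf("%s.%s.bedpe", s, k)))
    }
  }
  write_tsv_v(sim$meta, file.path(dir, "meta.tsv"), "sample-meta")
  write_tsv_v(sim$ct_regions, file.path(dir, "chromothripsis.tsv"),
              "chromothripsis-regions")
  write_tsv_v(sim$ledger, file.path(dir, "truth_ledger.tsv"), "truth-ledger")
  write_tsv_v(sim$scaffold$tads, file.path(dir, "tads.tsv"), "tads")
  write_tsv_v(sim$scaffold$boundaries, file.path(dir, "boundaries.tsv"),
              "tad-boundaries")
  write_tsv_v(sim$scaffold$genes, file.path(dir, "genes.tsv"), "genes")
  write_tsv_v(sim$scaffold$fragile_sites, file.path(dir, "fragile.tsv"),
              "fragile-sites")
  invisible(dir)
}

#' Write SV calls as a minimal SV VCF
#'
#' DEL/DUP and head-to-head INV records are written with symbolic ALT and
#' `END`; TRA and tail-to-tail INV junctions are written as BND mate pairs
#' in bracket notation. Round-trips through [read_sv_calls()].
#'
#' @param calls One sample's `sv_calls`.
#' @param path Output VCF path.
#' @param genome Optional `genome_ref` for contig header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", genome$chrom_names,
                          as.integer(genome$chrom_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  out <- character()
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    symbolic <- r$svtype %in% c("DEL", "DUP") ||
      (r$svtype == "INV" && r$orient1 == "+" && r$orient2 == "+")
    if (symbolic) {
      out <- c(out, sprintf("%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d",
                            r$chrom1, as.integer(r$pos1 + 1), i, r$svtype,
                            r$svtype, as.integer(r$pos2 + 1)))
    } else {
      mk <- function(chrom_l, pos_l, o_l, chrom_r, pos_r, o_r, id, mate) {
        pos1b <- if (o_l == "+") pos_l + 1 else pos_l + 2
        p <- if (o_r == "+") pos_r + 1 else pos_r + 2
        alt <- if (o_l == "+") {
          if (o_r == "+") sprintf("N]%s:%d]", chrom_r, p)
          else sprintf("N[%s:%d[", chrom_r, p)
        } else {
          if (o_r == "+") sprintf("]%s:%d]N", chrom_r, p)
          else sprintf("[%s:%d[N", chrom_r, p)
        }
        sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=%s;MATEID=%s",
                chrom_l, as.integer(pos1b), id, alt, r$svtype, mate)
      }
      id1 <- sprintf("bnd%d_1", i); id2 <- sprintf("bnd%d_2", i)
      out <- c(out,
               mk(r$chrom1, r$pos1, r$orient1, r$chrom2, r$pos2, r$orient2,
                  id1, id2),
               mk(r$chrom2, r$pos2, r$orient2, r$chrom1, r$pos1, r$orient1,
                  id2, id1))
    }
  }
  writeLines(c(hdr, out), path)
  invisible(path)
}
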