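#' @section Coordinate conventions:
#' Everything internal is 0-based half-open. A breakend is a (chrom, pos,
#' orient) triple where the junction lies in the gap between base `pos` and
#' base `pos + 1`: orient `"+"` means the derived allele retains the
#' reference bases up to and including `pos` (sequence left of the gap),
#' orient `"-"` means it retains the bases from `pos + 1` onward. VCF input
#' (1-based) is converted on read; BEDPE is native.
#'
#' @keywords internal
#' @name svmodes-conventions
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "TRA")

SV_CALL_COLS <- c("sample_id", "caller_id", "chrom1", "pos1", "orient1",
                  "chrom2", "pos2", "orient2", "svtype", "size")

#' Construct an SV call table
#'
#' Builds and validates the canonical SV call data frame used throughout the
#' package: one row per somatic rearrangement, as an oriented breakend pair.
#' Breakends are reordered so b1 precedes b2 by (chromosome order, position)
#' and `size` is recomputed as `pos2 - pos1` for intrachromosomal calls
#' (`NA` for interchromosomal ones, which are always `TRA`).
#'
#' @param sample_id,caller_id Character vectors (recycled).
#' @param chrom1,pos1,orient1,chrom2,pos2,orient2 Breakend fields; positions
#'   0-based, orientations in `c("+", "-")`.
#' @param svtype One of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @param chrom_order Optional character vector fixing chromosome order for
#'   breakend canonicalization; defaults to sorted unique chromosomes.
#' @return A `data.frame` with class `sv_calls`.
#' @export
sv_calls <- function(sample_id, caller_id, chrom1, pos1, orient1,
                     chrom2, pos2, orient2, svtype, chrom_order = NULL) {
  df <- data.frame(sample_id = as.character(sample_id),
                   caller_id = as.character(caller_id),
                   chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                   orient1 = as.character(orient1),
                   chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                   orient2 = as.character(orient2),
                   svtype = as.character(svtype),
                   stringsAsFactors = FALSE)
  canonicalize_breakends(df, chrom_order = chrom_order)
}

#' Canonicalize breakend order and recompute sizes
#'
#' @param df Data frame with the `sv_calls` breakend columns.
#' @param chrom_order Optional chromosome ordering.
#' @return The canonicalized `sv_calls` data frame.
#' @export
canonicalize_breakends <- function(df, chrom_order = NULL) {
  stopifnot(all(c("chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2",
                  "svtype") %in% names(df)))
  stopifnot(all(df$orient1 %in% c("+", "-")), all(df$orient2 %in% c("+", "-")),
            all(df$svtype %in% SV_TYPES))
  if (is.null(chrom_order))
    chrom_order <- sort(unique(c(df$chrom1, df$chrom2)))
  c1 <- match(df$chrom1, chrom_order)
  c2 <- match(df$chrom2, chrom_order)
  stopifnot(!anyNA(c1), !anyNA(c2))
  swap <- c2 < c1 | (c1 == c2 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom2", "pos2", "orient2")]
    df[swap, c("chrom2", "pos2", "orient2")] <-
      df[swap, c("chrom1", "pos1", "orient1")]
    df[swap, c("chrom1", "pos1", "orient1")] <- tmp
  }
  intra <- df$chrom1 == df$chrom2
  stopifnot(all(df$svtype[!intra] == "TRA"))
  df$size <- ifelse(intra, df$pos2 - df$pos1, NA_real_)
  rownames(df) <- NULL
  class(df) <- unique(c("sv_calls", class(df)))
  df
}

# orientation pair implied by a simple SV class; INV junctions come in
# head-to-head (+,+) and tail-to-tail (-,-) flavors, (+,+) is the default
.orients_for_type <- function(svtype) {
  switch(svtype,
         DEL = c("+", "-"), DUP = c("-", "+"), INV = c("+", "+"),
         TRA = c("+", "-"))
}

# classify a same-chromosome junction by its orientation pair
.type_from_orients <- function(o1, o2) {
  ifelse(o1 == "+" & o2 == "-", "DEL",
         ifelse(o1 == "-" & o2 == "+", "DUP", "INV"))
}

#' Read SV calls from VCF (breakend/symbolic) or BEDPE
#'
#' VCF support covers the two dialects emitted by short-read SV callers:
#' symbolic ALT records (`<DEL>`, `<DUP>`, `<INV>` with `END`/`SVLEN`) and
#' breakend (`BND`) records, whose mate pairs are resolved to single
#' junction records via the bracket notation in ALT. Records whose ALT
#' cannot be resolved are skipped with a warning; records with an unknown
#' SV type are dropped and counted in the `rejected` attribute.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"bedpe"`.
#' @param caller_id,sample_id Provenance labels attached to every call.
#' @param chrom_order Optional chromosome ordering for canonicalization.
#' @return An `sv_calls` data frame; attribute `rejected` holds the count of
#'   records dropped for unknown type.
#' @export
read_sv_calls <- function(path, format = c("vcf", "bedpe"),
                          caller_id, sample_id, chrom_order = NULL) {
  format <- match.arg(format)
  if (format == "vcf")
    .read_sv_vcf(path, caller_id, sample_id, chrom_order)
  else
    .read_sv_bedpe(path, caller_id, sample_id, chrom_order)
}

.empty_calls <- function() {
  df <- data.frame(sample_id = character(), caller_id = character(),
                   chrom1 = character(), pos1 = numeric(),
                   orient1 = character(), chrom2 = character(),
                   pos2 = numeric(), orient2 = character(),
                   svtype = character(), size = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("sv_calls", class(df))
  df
}

.read_sv_vcf <- function(path, caller_id, sample_id, chrom_order) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0) return(.empty_calls())
  fx <- strsplit(ln, "\t", fixed = TRUE)
  nf <- min(lengths(fx))
  stopifnot(nf >= 8)
  chrom <- vapply(fx, `[[`, "", 1L)
  pos <- as.numeric(vapply(fx, `[[`, "", 2L))
  alt <- vapply(fx, `[[`, "", 5L)
  info <- vapply(fx, `[[`, "", 8L)
  getinfo <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info)
    out[hit] <- sub(paste0("^.*?", key, "="), "", m)
    out
  }
  svtype_info <- getinfo("SVTYPE")
  end_info <- suppressWarnings(as.numeric(getinfo("END")))
  svlen_info <- suppressWarnings(as.numeric(getinfo("SVLEN")))

  sym <- grepl("^<(DEL|DUP|INV)>$", alt)
  bnd <- grepl("[\\[\\]]", alt, perl = TRUE)
  rejected <- sum(!sym & !bnd)
  rows <- list()

  if (any(sym)) {
    st <- sub("^<|>$", "", gsub("[<>]", "", alt[sym]))
    p1 <- pos[sym] - 1
    endv <- end_info[sym]
    fallback <- is.na(endv)
    endv[fallback] <- pos[sym][fallback] + abs(svlen_info[sym][fallback])
    if (anyNA(endv)) stop("symbolic ALT record without END or SVLEN")
    p2 <- endv - 1
    ors <- t(vapply(st, .orients_for_type, character(2)))
    rows$sym <- data.frame(chrom1 = chrom[sym], pos1 = p1, orient1 = ors[, 1],
                           chrom2 = chrom[sym], pos2 = p2, orient2 = ors[, 2],
                           svtype = st, stringsAsFactors = FALSE)
  }

  if (any(bnd)) {
    a <- alt[bnd]
    m <- regmatches(a, regexec("([A-Za-z.]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z.]*)",
                               a, perl = TRUE))
    ok <- lengths(m) == 7
    if (any(!ok))
      warning(sprintf("%d BND record(s) with unresolvable ALT skipped", sum(!ok)))
    m <- m[ok]
    bchrom <- chrom[bnd][ok]; bpos <- pos[bnd][ok]
    bstype <- svtype_info[bnd][ok]
    pre <- vapply(m, `[[`, "", 2L)   # leading bases (empty if bracket-first)
    br <- vapply(m, `[[`, "", 3L)    # bracket char
    mchrom <- vapply(m, `[[`, "", 4L)
    mpos <- as.numeric(vapply(m, `[[`, "", 5L))
    local_plus <- nzchar(pre)                 # t[p[ or t]p] forms
    mate_plus <- br == "]"                    # "]" joins mate's left side
    loc0 <- ifelse(local_plus, bpos - 1, bpos - 2)
    mat0 <- ifelse(mate_plus, mpos - 1, mpos - 2)
    st <- ifelse(bchrom != mchrom, "TRA",
                 ifelse(bstype %in% c("DEL", "DUP", "INV"), bstype,
                        ifelse(!is.na(bstype) & bstype == "TRA", "TRA",
                               .type_from_orients(
                                 ifelse(local_plus, "+", "-"),
                                 ifelse(mate_plus, "+", "-")))))
    rows$bnd <- data.frame(chrom1 = bchrom, pos1 = loc0,
                           orient1 = ifelse(local_plus, "+", "-"),
                           chrom2 = mchrom, pos2 = mat0,
                           orient2 = ifelse(mate_plus, "+", "-"),
                           svtype = st, stringsAsFactors = FALSE)
  }

  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0) {
    out <- .empty_calls()
    attr(out, "rejected") <- rejected
    return(out)
  }
  df$sample_id <- sample_id
  df$caller_id <- caller_id
  df <- canonicalize_breakends(df, chrom_order = chrom_order)
  # the two mates of one BND junction collapse to the same canonical record
  key <- with(df, paste(chrom1, pos1, orient1, chrom2, pos2, orient2, svtype))
  df <- df[!duplicated(key), SV_CALL_COLS]
  class(df) <- unique(c("sv_calls", class(df)))
  attr(df, "rejected") <- rejected
  rownames(df) <- NULL
  df
}

.read_sv_bedpe <- function(path, caller_id, sample_id, chrom_order) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(df) == 0) return(.empty_calls())
  for (j in intersect(c(1, 4, 7:11), seq_len(ncol(df))))
    df[[j]] <- as.character(df[[j]])
  stopifnot(ncol(df) >= 10)
  out <- data.frame(chrom1 = df[[1]], pos1 = df[[2]], orient1 = df[[9]],
                    chrom2 = df[[4]], pos2 = df[[5]], orient2 = df[[10]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 11 && !all(is.na(df[[11]]))) {
    out$svtype <- as.character(df[[11]])
  } else {
    out$svtype <- ifelse(out$chrom1 != out$chrom2, "TRA",
                         .type_from_orients(out$orient1, out$orient2))
  }
  bad <- !(out$svtype %in% SV_TYPES)
  if (any(bad)) out <- out[!bad, , drop = FALSE]
  out$sample_id <- sample_id
  out$caller_id <- caller_id
  out <- canonicalize_breakends(out, chrom_order = chrom_order)[, SV_CALL_COLS]
  class(out) <- unique(c("sv_calls", class(out)))
  attr(out, "rejected") <- sum(bad)
  out
}

#' Write SV calls as BEDPE
#'
#' Writes the package's BEDPE dialect: the ten standard columns (breakends
#' as 1-bp intervals) plus an eleventh `svtype` column and a twelfth
#' `sample_id` column, preceded by a versioned comment header. Re-reading
#' with [read_sv_calls()] reproduces every breakend, type, and size.
#'
#' @param calls An `sv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  df <- data.frame(calls$chrom1, calls$pos1, calls$pos1 + 1,
                   calls$chrom2, calls$pos2, calls$pos2 + 1,
                   name = sprintf("sv%06d", seq_len(nrow(calls))),
                   score = ".", strand1 = calls$orient1,
                   strand2 = calls$orient2, svtype = calls$svtype,
                   sample_id = calls$sample_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#svmodes bedpe v1: chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2 svtype sample_id", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a versioned TSV table
#'
#' All tabular outputs use a TSV with a first comment line identifying the
#' table kind and format version.
#'
#' @param df Data frame.
#' @param path File path.
#' @param what Table kind tag written into the header line.
#' @return `path` (write) or a data frame (read).
#' @export
write_tsv_v <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#svmodes %s v1", what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_v
#' @export
read_tsv_v <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a BED-like interval table
#'
#' Plain BED (0-based half-open) with an optional fourth name column and
#' further extra columns, returned under caller-chosen names.
#'
#' @param path BED file.
#' @param extra_cols Names for columns 4, 5, ... when present.
#' @return Data frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = character()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  nex <- min(length(extra_cols), ncol(df) - 3)
  if (nex > 0) names(df)[3 + seq_len(nex)] <- extra_cols[seq_len(nex)]
  stopifnot(all(df$start < df$end))
  df
}

#' Sample-level quality-control filter
#'
#' Retains samples with coverage at least `min_cov` (applied to
#' `coverage` and, when the column is present, `normal_coverage`) and
#' purity at least `min_purity`; both thresholds inclusive. Samples with
#' missing purity or coverage are excluded and listed in the `qc_report`
#' attribute of the result.
#'
#' @param samples Sample metadata data frame with at least `sample_id`,
#'   `coverage`, `purity`.
#' @param min_cov Minimum fold coverage (default 20).
#' @param min_purity Minimum tumor purity fraction (default 0.20).
#' @return The retained rows; attribute `qc_report` is a data frame of
#'   excluded samples with a `reason` column.
#' @export
qc_filter <- function(samples, min_cov = 20, min_purity = 0.20) {
  stopifnot(all(c("sample_id", "coverage", "purity") %in% names(samples)))
  reason <- rep(NA_character_, nrow(samples))
  miss <- is.na(samples$purity) | is.na(samples$coverage)
  reason[miss] <- "missing coverage or purity"
  low_cov <- !miss & samples$coverage < min_cov
  if ("normal_coverage" %in% names(samples))
    low_cov <- low_cov | (!miss & !is.na(samples$normal_coverage) &
                            samples$normal_coverage < min_cov)
  reason[low_cov & is.na(reason)] <- "coverage below threshold"
  low_pur <- !miss & samples$purity < min_purity
  reason[low_pur & is.na(reason)] <- "purity below threshold"
  keep <- is.na(reason)
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- data.frame(sample_id = samples$sample_id[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "qc_report") <- report
  out
}

#' Mutational-signature presence call
#'
#' A signature is called present in a sample when its refit contribution is
#' at least `cutoff` (inclusive; default 0.06, the recommended refitting
#' cutoff). Contributions are read from metadata columns named
#' `sig<signature_id>`; a missing column or `NA` counts as 0.
#'
#' @param meta Sample metadata data frame.
#' @param signature_id Signature number or name (e.g. `3` or `"3"`).
#' @param cutoff Presence cutoff on the contribution fraction.
#' @return Logical vector, one entry per metadata row.
#' @export
signature_present <- function(meta, signature_id, cutoff = 0.06) {
  col <- paste0("sig", signature_id)
  if (!col %in% names(meta)) return(rep(FALSE, nrow(meta)))
  x <- meta[[col]]
  x[is.na(x)] <- 0
  x >= cutoff
}
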