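#' Genome reference object
#'
#' A lightweight reference-genome handle holding chromosome names, lengths,
#' and (optionally) sequence. Sequence is stored as raw byte vectors so the
#' synthetic-cohort generator can plant junction flanks in place; all query
#' functions return uppercase character strings over \{A,C,G,T,N\}.
#'
#' All coordinates in this package are 0-based half-open.
#'
#' @param chrom_names Character vector of chromosome identifiers.
#' @param chrom_lengths Integer vector of chromosome lengths (bp), same
#'   length as `chrom_names`. Must be strictly positive.
#' @param seqs Optional named list of sequences, one per chromosome, each a
#'   single character string or a raw vector of ASCII bases.
#' @return An object of class `genome_ref`.
#' @export
genome_ref <- function(chrom_names, chrom_lengths, seqs = NULL) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  stopifnot(length(chrom_names) == length(chrom_lengths),
            !anyDuplicated(chrom_names),
            all(chrom_lengths > 0))
  names(chrom_lengths) <- chrom_names
  if (!is.null(seqs)) {
    stopifnot(all(chrom_names %in% names(seqs)))
    seqs <- lapply(seqs[chrom_names], function(s) {
      if (is.character(s)) s <- charToRaw(toupper(s))
      stopifnot(is.raw(s))
      s
    })
    stopifnot(all(lengths(seqs) == chrom_lengths))
  }
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = chrom_lengths,
                 seqs = seqs),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("genome_ref: %d chromosome(s), %.3g Mb total, sequence %s\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6,
              if (is.null(x$seqs)) "absent" else "loaded"))
  invisible(x)
}

#' Load a genome reference from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `genome_ref` with sequence loaded.
#' @export
genome_from_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  seqs <- lapply(seq_along(dss), function(i) charToRaw(toupper(as.character(dss[[i]]))))
  names(seqs) <- nm
  genome_ref(nm, Biostrings::width(dss), seqs)
}

#' Write a genome reference to FASTA
#'
#' @param genome A `genome_ref` with sequence loaded.
#' @param path Output FASTA path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_ref"), !is.null(genome$seqs))
  dss <- Biostrings::DNAStringSet(vapply(genome$seqs, rawToChar, ""))
  names(dss) <- genome$chrom_names
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Fetch genome sequence
#'
#' Returns the bases of `[start, end)` (0-based half-open) on `chrom`.
#' Queries beyond chromosome ends are clipped; the clipped-off part is
#' reported as `N` padding so that the returned string always has length
#' `end - start`. `strand = "-"` returns the reverse complement.
#'
#' @param genome A `genome_ref` with sequence.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` (default) or `"-"`.
#' @return A single uppercase character string.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_ref"), !is.null(genome$seqs),
            chrom %in% genome$chrom_names, end >= start)
  L <- genome$chrom_lengths[[chrom]]
  s <- max(0, start); e <- min(L, end)
  core <- if (e > s) rawToChar(genome$seqs[[chrom]][(s + 1):e]) else ""
  out <- paste0(strrep("N", s - start), core, strrep("N", end - e))
  if (strand == "-") out <- revcomp(out)
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character string over \{A,C,G,T,N\} (case-insensitive).
#' @return Reverse-complemented uppercase string.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# in-place-ish byte edit; base must be a single uppercase character
.genome_set_base <- function(genome, chrom, pos, base) {
  stopifnot(pos >= 0, pos < genome$chrom_lengths[[chrom]])
  genome$seqs[[chrom]][pos + 1] <- charToRaw(base)
  genome
}

# raw-byte complement lookup (A<->T, C<->G, everything else -> N)
.COMP_TABLE <- local({
  tab <- rep(charToRaw("N"), 256)
  for (p in list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"),
                 c("a", "T"), c("t", "A"), c("c", "G"), c("g", "C"),
                 c("N", "N")))
    tab[as.integer(charToRaw(p[1])) + 1] <- charToRaw(p[2])
  tab
})

# fast raw-vector sequence fetch in junction frame; out-of-range positions
# padded with N. 0-based half-open; strand "-" returns reverse complement.
.genome_seq_raw <- function(genome, chrom, start, end, strand = "+") {
  L <- genome$chrom_lengths[[chrom]]
  s <- max(0, start); e <- min(L, end)
  core <- if (e > s) genome$seqs[[chrom]][(s + 1):e] else raw(0)
  npad <- charToRaw("N")
  out <- c(rep(npad, s - start), core, rep(npad, end - e))
  if (strand == "-") out <- rev(.COMP_TABLE[as.integer(out) + 1])
  out
}
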