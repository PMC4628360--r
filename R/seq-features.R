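# Sequence-composition features: AT content, maximal AT stretches, CpG
# dinucleotide counts, and the per-gene feature table.

.as_seq_string <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L) {
    stop("expected a single DNA sequence")
  }
  toupper(seq)
}

#' AT content of a sequence
#'
#' \code{(A + T) / (A + C + G + T)}; ambiguous bases (\code{N}) are
#' excluded from the denominator.
#'
#' @param seq DNA sequence (character, \code{DNAString}, or length-1
#'   \code{DNAStringSet}); alphabet \code{A, C, G, T, N}, case-insensitive.
#' @return Fraction in \code{[0, 1]}.
#' @export
atContent <- function(seq) {
  s <- .as_seq_string(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((counts[["A"]] + counts[["T"]]) / denom)
}

#' Count maximal AT stretches
#'
#' Number of maximal runs of consecutive \code{A}/\code{T} bases of length
#' at least \code{min_len}; any other character (including \code{N})
#' breaks a run. The run-length threshold is a reporting parameter, not a
#' biological constant, and is printed alongside any stretch counts the
#' pipeline emits.
#'
#' @inheritParams atContent
#' @param min_len Minimum run length in bp (>= 2; default 8).
#' @return Non-negative integer count.
#' @export
countAtStretches <- function(seq, min_len = 8L) {
  .assert_scalar_number(min_len, "min_len", lower = 2)
  s <- .as_seq_string(seq)
  if (nchar(s) == 0L) return(0L)
  pat <- sprintf("[AT]{%d,}", as.integer(min_len))
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Count CpG dinucleotides
#'
#' Occurrences of the dinucleotide \code{CG} (5'->3'); orientation
#' matters, so \code{GC} does not count. Occurrences cannot overlap by
#' construction.
#'
#' @inheritParams atContent
#' @return Non-negative integer count.
#' @export
countCpg <- function(seq) {
  s <- .as_seq_string(seq)
  if (nchar(s) < 2L) return(0L)
  Biostrings::countPattern("CG", Biostrings::DNAString(s))
}

#' Per-gene sequence feature table
#'
#' Extracts each gene's sequence from the genome and reports length, AT
#' content, number of maximal AT stretches (at the stated \code{min_len})
#' and CpG count -- the columns of a large-gene fragility table. Features
#' are computed on the reference (plus) strand; AT content and CpG count
#' are invariant under reverse complement.
#'
#' @param genes Gene \code{GRanges} with \code{gene_id}.
#' @param fasta Named \code{DNAStringSet} (see [readGenomeFasta()]).
#' @param min_len AT-stretch minimum length in bp (default 8).
#' @return \code{data.frame}: \code{gene_id}, \code{length_bp},
#'   \code{at_fraction}, \code{n_at_stretches}, \code{n_cpg},
#'   \code{at_stretch_min_len}.
#' @export
geneFeatureTable <- function(genes, fasta, min_len = 8L) {
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  missing_chrom <- setdiff(unique(chrom), names(fasta))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from FASTA: ",
         paste(missing_chrom, collapse = ", "))
  }
  ids <- S4Vectors::mcols(genes)$gene_id
  rows <- lapply(seq_along(genes), function(i) {
    len_chr <- length(fasta[[chrom[i]]])
    s <- GenomicRanges::start(genes)[i]
    e <- GenomicRanges::end(genes)[i]
    if (e > len_chr) {
      stop(sprintf("gene '%s' extends beyond the end of %s (%d > %d)",
                   ids[i], chrom[i], e, len_chr))
    }
    seq <- as.character(Biostrings::subseq(fasta[[chrom[i]]], start = s, end = e))
    data.frame(
      gene_id = ids[i],
      length_bp = e - s + 1L,
      at_fraction = atContent(seq),
      n_at_stretches = countAtStretches(seq, min_len),
      n_cpg = countCpg(seq),
      at_stretch_min_len = as.integer(min_len),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
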