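# Independent brute-force oracles used by the property tests. These work on
# plain data.frames of 1-based closed intervals (chrom, start, end) and use
# only loops and base arithmetic, so they share no code path with the
# GRanges-based implementation.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
  library(GenomeInfoDb)
  library(GenomicRanges)
})

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# shared bases between two 1-based closed intervals on the same chromosome
bf_overlap_width <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# all-pairs overlap scan: indices of df rows overlapping the query by >= mo
bf_overlap_query <- function(df, qchrom, qstart, qend, mo = 1L) {
  hits <- integer()
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != qchrom) next
    if (bf_overlap_width(df$start[i], df$end[i], qstart, qend) >= mo) {
      hits <- c(hits, i)
    }
  }
  hits
}

# per-base bitmap of covered positions on a toy chromosome of length L
bf_bitmap <- function(df, chrom, L) {
  mask <- logical(L)
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != chrom) next
    mask[df$start[i]:min(df$end[i], L)] <- TRUE
  }
  mask
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), L = 10000L,
                             max_w = 500L) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(L - wi, 1L), 0L)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w - 1L, stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$peak_id <- sprintf("p%03d", seq_len(nrow(df)))
  gr
}

# run-length AT-stretch counter independent of the regex implementation
rle_at_stretches <- function(seq, min_len) {
  ch <- strsplit(toupper(seq), "")[[1]]
  r <- rle(ch %in% c("A", "T"))
  sum(r$values & r$lengths >= min_len)
}

# sliding-window CpG counter
window_cpg <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < 2) return(0L)
  sum(ch[-n] == "C" & ch[-1] == "G")
}

revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "")[[1]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
}

random_dna_string <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# small gene set builder (0-based half-open inputs, matching the readers)
make_genes <- function(chrom, start0, end0, strand, biotype) {
  geneGRanges(sprintf("g%03d", seq_along(start0)), chrom, start0, end0,
              strand, biotype)
}
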