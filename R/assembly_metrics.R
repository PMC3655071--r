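#' N50 of a set of contig lengths
#'
#' The length L such that contigs of length >= L together contain at least
#' half of the total bases: descending-sort cumulative-sum convention,
#' returning the length at which the cumulative sum first reaches total/2.
#'
#' @param lengths positive integer lengths (non-empty).
#' @return the N50, an integer.
#' @examples
#' n50(c(80, 70, 50, 40, 30, 20)) # 70
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1L]])
}

.base_counts <- function(seqs) {
  cnt <- function(p) nchar(seqs) - nchar(gsub(p, "", seqs))
  cbind(A = cnt("A"), C = cnt("C"), G = cnt("G"), T = cnt("T"))
}

#' GC fraction of sequences
#'
#' (G + C) / (A + C + G + T); N and other ambiguity codes are excluded from
#' the denominator. A sequence with no unambiguous base is an error.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return numeric GC fractions in \[0, 1\].
#' @export
gc_fraction <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (!length(seqs) || any(!nchar(seqs))) stop("empty sequence")
  b <- .base_counts(seqs)
  tot <- rowSums(b)
  if (any(tot == 0)) stop("sequence with no unambiguous bases")
  unname((b[, "G"] + b[, "C"]) / tot)
}

#' Normalized GC histogram
#'
#' Per-sequence GC content binned at `bin_width`; bin masses sum to 1.
#' Computed identically for reads and contigs so the two distributions are
#' directly comparable (the read histogram is expression-weighted by
#' construction — an abundant gene contributes many reads but one contig —
#' which is what makes the read/contig GC offset visible).
#'
#' @param seqs character vector of sequences (non-empty).
#' @param bin_width bin width; must divide 1 evenly.
#' @return data frame with `bin_low`, `bin_high`, `mass`.
#' @export
gc_histogram <- function(seqs, bin_width = 0.05) {
  if (!length(seqs)) stop("empty input")
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1 evenly")
  nb <- as.integer(round(nb))
  gc <- gc_fraction(seqs)
  bin <- pmin(nb, floor(gc / bin_width) + 1L)  # gc == 1 goes in the top bin
  mass <- tabulate(bin, nbins = nb) / length(gc)
  data.frame(bin_low = (seq_len(nb) - 1L) * bin_width,
             bin_high = seq_len(nb) * bin_width, mass = mass)
}

#' Per-assembly summary statistics
#'
#' One row of the saturation table's assembly side: transcript and locus
#' counts, length statistics (mean, median, N50), per-million-read rates and
#' GC. The scalar GC is pooled over bases (total G+C over total unambiguous
#' bases); the per-sequence view is available via [gc_histogram()]. An empty
#' assembly yields zero counts and NA means.
#'
#' @param assembly an `assembly` (from [assemble()] or [as_assembly()]).
#' @param depth_reads the read count behind the assembly (> 0); used for the
#'   per-million columns.
#' @return one-row data frame with columns `depth_reads`, `n_transcripts`,
#'   `total_length_bp`, `mean_bp`, `median_bp`, `n50_bp`, `n_loci`,
#'   `loci_per_million_reads`, `transcripts_per_million_reads`,
#'   `transcripts_per_locus`, `gc_percent`.
#' @export
assembly_metrics <- function(assembly, depth_reads) {
  if (is.na(depth_reads) || depth_reads <= 0)
    stop("depth_reads must be > 0")
  lens <- nchar(assembly$contigs)
  n <- length(lens)
  if (n == 0L)
    return(data.frame(depth_reads = depth_reads, n_transcripts = 0L,
                      total_length_bp = 0, mean_bp = NA_real_,
                      median_bp = NA_real_, n50_bp = NA_integer_,
                      n_loci = 0L, loci_per_million_reads = 0,
                      transcripts_per_million_reads = 0,
                      transcripts_per_locus = NA_real_,
                      gc_percent = NA_real_))
  b <- .base_counts(assembly$contigs)
  n_loci <- length(unique(assembly$locus))
  data.frame(depth_reads = depth_reads, n_transcripts = n,
             total_length_bp = sum(lens), mean_bp = sum(lens) / n,
             median_bp = stats::median(lens), n50_bp = n50(lens),
             n_loci = n_loci,
             loci_per_million_reads = n_loci / (depth_reads / 1e6),
             transcripts_per_million_reads = n / (depth_reads / 1e6),
             transcripts_per_locus = n / n_loci,
             gc_percent = 100 * sum(b[, c("G", "C")]) / sum(b))
}

#' @export
summary.assembly <- function(object, depth_reads = object$n_input_reads, ...) {
  assembly_metrics(object, depth_reads)
}
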