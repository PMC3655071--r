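#' Assembly parameters for the de Bruijn stand-in assembler
#'
#' @param k odd k-mer size >= 15 (must be below the read length).
#' @param coverage_cutoff static k-mer coverage cutoff: k-mers observed fewer
#'   times are removed before graph construction. The contrast between a
#'   permissive cutoff of 3 and a strict cutoff of 10 is the C3/C10 contrast
#'   the pipeline is built to explore.
#' @param min_contig_length contigs shorter than this are discarded
#'   (default 100, a typical read length).
#' @return an `assembly_params` list.
#' @export
assembly_params <- function(k = 21L, coverage_cutoff = 3L,
                            min_contig_length = 100L) {
  k <- as.integer(k)
  if (k < 15L || k %% 2L == 0L) stop("k must be an odd integer >= 15")
  if (coverage_cutoff < 1L) stop("coverage_cutoff must be >= 1")
  structure(list(k = k, coverage_cutoff = as.integer(coverage_cutoff),
                 min_contig_length = as.integer(min_contig_length)),
            class = "assembly_params")
}

.read_seqs <- function(reads) {
  if (inherits(reads, "read_set") || is.data.frame(reads)) reads$seq
  else as.character(reads)
}

#' Count canonical k-mers
#'
#' Both strands are collapsed onto the lexicographically smaller of a k-mer
#' and its reverse complement; k-mers containing N are skipped.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param k k-mer size.
#' @return named integer vector of canonical k-mer counts.
#' @export
count_kmers <- function(reads, k) {
  count_kmers_cpp(.read_seqs(reads), as.integer(k))
}

#' Assemble reads into unitigs with a static coverage cutoff
#'
#' A deliberately small stand-in for a production transcriptome assembler:
#' canonical k-mers below `coverage_cutoff` are dropped, the remaining k-mers
#' form a bidirected de Bruijn graph, and contigs are its maximal
#' non-branching paths (unitigs). There is no bubble resolution, scaffolding
#' or isoform traversal, so "transcripts per locus" here reflects unitig
#' fragmentation rather than splice variants. Deterministic: contig
#' orientation is the lexicographically smaller strand and output order is
#' fixed (longest first).
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param params an [assembly_params()].
#' @return an `assembly`: list with `contigs` (named character), `locus`
#'   (named character, contig id to locus label; contigs sharing a canonical
#'   k-mer share a locus), `n_input_reads`, `params`.
#' @export
assemble <- function(reads, params = assembly_params()) {
  seqs <- .read_seqs(reads)
  if (length(seqs) && params$k >= min(nchar(seqs)))
    stop("k must be smaller than the read length")
  contigs <- assemble_dbg_cpp(seqs, params$k, params$coverage_cutoff,
                              params$min_contig_length)
  names(contigs) <- sprintf("contig%05d", seq_along(contigs))
  structure(list(contigs = contigs,
                 locus = cluster_loci(contigs, params$k),
                 n_input_reads = length(seqs), params = params),
            class = "assembly")
}

#' Group contigs into loci by shared k-mers
#'
#' Connected components of the graph linking two contigs iff they share at
#' least one canonical k-mer — the stand-in for an assembler's gene-level
#' locus clustering. Disjoint contigs form singleton loci.
#'
#' @param contigs named character vector of contig sequences.
#' @param k k-mer size used for sharing.
#' @return named character vector: contig id -> locus label.
#' @export
cluster_loci <- function(contigs, k) {
  if (!length(contigs))
    return(setNames(character(), character()))
  comp <- cluster_loci_cpp(as.character(contigs), as.integer(k))
  setNames(sprintf("locus%05d", comp), names(contigs))
}

#' Wrap externally assembled contigs
#'
#' Entry point for real assemblies supplied as FASTA: anywhere the pipeline
#' consumes an assembly, contigs from any assembler can stand in for the
#' built-in one. Without locus labels each contig is its own locus.
#'
#' @param contigs named character vector of contig sequences.
#' @param locus optional named character vector contig id -> locus label.
#' @param n_input_reads read count behind the assembly, if known.
#' @return an `assembly` object.
#' @export
as_assembly <- function(contigs, locus = NULL, n_input_reads = NA_integer_) {
  contigs <- unlist(contigs)
  if (is.null(contigs)) contigs <- setNames(character(), character())
  if (length(contigs) &&
      (is.null(names(contigs)) || anyDuplicated(names(contigs))))
    stop("contigs must have unique names")
  if (is.null(locus))
    locus <- setNames(sprintf("locus%05d", seq_along(contigs)), names(contigs))
  if (!all(names(contigs) %in% names(locus)))
    stop("every contig needs a locus label")
  structure(list(contigs = contigs, locus = locus[names(contigs)],
                 n_input_reads = n_input_reads, params = "external"),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly:", length(x$contigs), "contigs in",
      length(unique(x$locus)), "loci")
  if (!is.na(x$n_input_reads)) cat(" from", x$n_input_reads, "reads")
  cat("\n")
  if (length(x$contigs))
    cat("  lengths:", min(nchar(x$contigs)), "-", max(nchar(x$contigs)),
        "bp, N50", n50(nchar(x$contigs)), "bp\n")
  invisible(x)
}

#' Reverse complement
#'
#' @param seqs character vector of nucleotide sequences.
#' @return reverse complements (N maps to N).
#' @export
revcomp <- function(seqs) revcomp_cpp(as.character(seqs))
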