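#' Decode and encode Phred+33 quality strings
#'
#' Quality scores are stored internally as their ASCII (Phred+33) string form;
#' these helpers convert a single string to a vector of integer scores and
#' back. Encoding then decoding is lossless for scores in 0..93.
#'
#' @param qual a single quality string (ASCII, offset 33).
#' @return `phred_decode()`: an integer vector of Phred scores.
#' @examples
#' phred_decode("IIII") # 40 40 40 40
#' @export
phred_decode <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1L)
  v <- utf8ToInt(qual) - 33L
  if (any(v < 0L)) stop("quality character below '!': not Phred+33")
  v
}

#' @rdname phred_decode
#' @param scores integer vector of Phred scores (>= 0).
#' @return `phred_encode()`: a single ASCII quality string.
#' @export
phred_encode <- function(scores) {
  scores <- as.integer(scores)
  if (any(scores < 0L)) stop("negative Phred score")
  intToUtf8(scores + 33L)
}

#' Construct a read set
#'
#' A read set is a data frame with one row per read and columns `id`, `seq`,
#' `qual` (ASCII Phred+33 string, same length as `seq`), `mate` (1, 2, or 0
#' for unpaired) and `pair` (an integer unit label; the two mates of a pair
#' share it and always travel together through randomization and
#' subsampling).
#'
#' @param id,seq,qual,mate,pair parallel vectors as described above.
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual, mate = 0L, pair = seq_along(id)) {
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   qual = as.character(qual), mate = as.integer(mate),
                   pair = as.integer(pair), stringsAsFactors = FALSE)
  bad <- which(nchar(df$seq) != nchar(df$qual))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", bad[1L])
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x), "reads in", length(unique(x$pair)), "units\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

.strip_mate_suffix <- function(id) sub("[/ ][12]$", "", sub("\\s.*$", "", id))

#' Read and write FASTQ
#'
#' Strict 4-line FASTQ, Phred+33. Malformed records (short record, missing
#' `@`/`+` markers, quality string whose length differs from the sequence)
#' abort with an error naming the 1-based record index. Mate suffixes `/1`,
#' `/2` and SRA-style space-delimited descriptions are stripped from ids;
#' pairing across two files is positional.
#'
#' @param path path to a FASTQ file (may be gzipped).
#' @param mate mate flag to assign (0 = unpaired).
#' @return a [read_set()].
#' @export
read_fastq <- function(path, mate = 0L) {
  lines <- readLines(path)
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L, " in ", path)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(read_set(character(), character(), character(), integer(), integer()))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hd, 1L, 1L) != "@" | substr(pl, 1L, 1L) != "+")
  if (length(bad)) stop("malformed FASTQ record ", bad[1L], " in ", path)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("quality/sequence length mismatch at FASTQ record ", bad[1L],
         " in ", path)
  if (any(grepl("[^!-~]", ql)))
    warning("non-printable quality characters found; not valid Phred+33")
  read_set(.strip_mate_suffix(substring(hd, 2L)), toupper(sq), ql,
           mate = rep(as.integer(mate), n))
}

#' @rdname read_fastq
#' @param path1,path2 paths to the mate-1 and mate-2 FASTQ files.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1, mate = 1L)
  r2 <- read_fastq(path2, mate = 2L)
  if (nrow(r1) != nrow(r2))
    stop("paired FASTQ files differ in record count: ",
         nrow(r1), " vs ", nrow(r2))
  n <- nrow(r1)
  idx <- rep(seq_len(n), each = 2L)
  out <- rbind(as.data.frame(r1), as.data.frame(r2))[
    as.vector(rbind(seq_len(n), n + seq_len(n))), ]
  out$pair <- idx
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' @rdname read_fastq
#' @param reads a [read_set()].
#' @export
write_fastq <- function(reads, path) {
  suff <- ifelse(reads$mate %in% c(1L, 2L), paste0("/", reads$mate), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id, suff),
                             reads$seq, "+", reads$qual)), con)
  invisible(path)
}

#' @rdname read_fastq
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  write_fastq(reads[reads$mate == 1L, , drop = FALSE], path1)
  write_fastq(reads[reads$mate == 2L, , drop = FALSE], path2)
  invisible(c(path1, path2))
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings that present sequences as a plain named
#' character vector. Ids are truncated at the first whitespace; duplicate ids
#' raise a warning; an empty file yields an empty vector.
#'
#' @param path path to a FASTA file.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out)))
    warning("duplicate FASTA ids in ", path)
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Tabular output
#'
#' All tabular pipeline outputs are tab-separated with a header row and no
#' quoting or row names.
#'
#' @param df a data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
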