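# shared in-code fixtures

# error-free reads at every start position, repeated `fold` times: terminal
# k-mers are observed exactly `fold` times, interior ones more
tiling_reads <- function(seq, read_len = 100L, fold = 1L) {
  starts <- seq_len(nchar(seq) - read_len + 1L)
  rep(substring(seq, starts, starts + read_len - 1L), fold)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random transcript guaranteed to have no repeated canonical k-mer
unique_kmer_transcript <- function(len, k) {
  repeat {
    s <- random_dna(len)
    km <- substring(s, 1:(len - k + 1L), k:len)
    if (!anyDuplicated(pmin(km, depthsat::revcomp(km)))) return(s)
  }
}

# quality strings at a constant score
flat_qual <- function(len, q = 40L) depthsat::phred_encode(rep(q, len))

# a minimal read_set of clean random reads
clean_reads <- function(n, len = 60L, q = 40L) {
  depthsat::read_set(sprintf("r%03d", seq_len(n)),
                     vapply(seq_len(n), function(i) random_dna(len), ""),
                     rep(flat_qual(len, q), n))
}
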