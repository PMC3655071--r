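# Independent oracles, kept deliberately naive: definitional implementations
# used to cross-check the package's optimized paths.

# N50 straight from the definition: the largest length L present in the list
# such that contigs of length >= L hold at least half of the total bases.
n50_brute <- function(lengths) {
  tot <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  min(lengths)
}

# Affine-gap Smith-Waterman (Gotoh) score by direct dynamic programming.
# Gap of length g costs open + g * ext, the same convention as the package's
# alignment engine.
sw_gotoh_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    srow <- mat[av[i - 1L], bv]
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F_[i, j] <- max(H[i - 1L, j] - open - ext, F_[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + srow[j - 1L], E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# union-find connectivity oracle: partition contigs by shared canonical k-mer
loci_brute <- function(contigs, k) {
  n <- length(contigs)
  canon_kmers <- function(s) {
    if (nchar(s) < k) return(character())
    km <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    km <- km[!grepl("[^ACGT]", km)]
    unique(pmin(km, depthsat::revcomp(km)))
  }
  sets <- lapply(contigs, canon_kmers)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (length(intersect(sets[[i]], sets[[j]]))) {
      ri <- find(i); rj <- find(j)
      parent[max(ri, rj)] <- min(ri, rj)
    }
  vapply(seq_len(n), find, 1L)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_aa <- function(n, alphabet = rownames(blosum62())[1:20]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
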