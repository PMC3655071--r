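## Conserved-gene completeness scoring: a tblastn-style translated search of
## ortholog clusters against contigs, ORF extraction requiring both start and
## stop codons, best-alignment selection, and the ratio-based size-range
## classification into five length classes.

.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

# Karlin-Altschul constants for gapped BLOSUM62 (gap open 11 / extend 1)
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Six-frame translation
#'
#' Standard genetic code, stop codons rendered as `*`, trailing partial
#' codons dropped; frames -1..-3 translate the reverse complement. Ambiguous
#' codons translate to `X`.
#'
#' @param seq a single nucleotide sequence (length >= 3).
#' @return named character vector of 6 amino-acid strings
#'   (`+1 +2 +3 -1 -2 -3`).
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  ft <- .frames_table(setNames(seq, "x"))
  setNames(ft$aa, ifelse(ft$frame > 0, paste0("+", ft$frame), ft$frame))
}

# all six frames of a set of contigs as one long-format data frame
.frames_table <- function(contigs) {
  dna <- Biostrings::DNAStringSet(unlist(contigs))
  rc <- Biostrings::reverseComplement(dna)
  out <- vector("list", 6L)
  i <- 0L
  for (ori in c(1L, -1L)) {
    src <- if (ori > 0L) dna else rc
    for (f in 1:3) {
      w <- Biostrings::width(src)
      aalen <- pmax(0L, (w - f + 1L) %/% 3L)
      ss <- Biostrings::subseq(src, start = pmin(f, w + 1L), width = 3L * aalen)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(ss, if.fuzzy.codon = "X")))
      i <- i + 1L
      out[[i]] <- data.frame(contig_id = names(contigs), frame = ori * f,
                             aa = unname(aa), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Ratio-based full-length size bounds for an ortholog cluster
#'
#' With S1 <= S2 the two shortest member lengths and L1 >= L2 the two
#' longest, the full-length window is `[floor(S1 * S1/S2), ceiling(L1 *
#' L1/L2)]`: the spread between the two extreme members is extrapolated one
#' step further to admit proteins that could plausibly become the new
#' shortest or longest member. A cluster whose shortest members are 80 and
#' 100 aa gets a lower bound of 64 aa.
#'
#' @param member_lengths at least two member protein lengths (aa).
#' @return named integer vector `c(lower = , upper = )`.
#' @examples
#' size_bounds(c(80, 100, 120)) # lower 64
#' @export
size_bounds <- function(member_lengths) {
  member_lengths <- as.numeric(member_lengths)
  if (length(member_lengths) < 2L) stop("need at least two member lengths")
  s <- sort(member_lengths)
  n <- length(s)
  c(lower = as.integer(floor(s[1L] * s[1L] / s[2L])),
    upper = as.integer(ceiling(s[n] * s[n] / s[n - 1L])))
}

#' Classify an extracted protein by length against the cluster's size range
#'
#' Exactly one of five classes: `WITHIN_RANGE` (inside the bounds, alignment
#' covering at least 90% of the protein), `WITHIN_RANGE_SHORT_ALIGN` (inside
#' the bounds, alignment shorter than that), `TOO_LONG` (above the upper
#' bound), `TOO_SHORT` (below the lower bound but at least as long as the
#' alignment), `SHORTER_THAN_ALIGNMENT` (below the lower bound and shorter
#' than the alignment — typically a stop codon bridged by the alignment).
#' Only `WITHIN_RANGE` counts as full-length.
#'
#' @param protein_len_aa extracted protein length(s), aa (> 0), stop
#'   excluded.
#' @param aligned_length_aa aligned length(s) in reference-protein residues.
#' @param bounds `c(lower, upper)` from [size_bounds()].
#' @return character vector of class labels (vectorized over the first two
#'   arguments).
#' @export
classify_length <- function(protein_len_aa, aligned_length_aa, bounds) {
  len <- as.numeric(protein_len_aa)
  aln <- as.numeric(aligned_length_aa)
  if (any(len <= 0)) stop("protein_len_aa must be > 0")
  lower <- bounds[[1L]]; upper <- bounds[[2L]]
  ifelse(len > upper, "TOO_LONG",
  ifelse(len < lower, ifelse(len < aln, "SHORTER_THAN_ALIGNMENT", "TOO_SHORT"),
  ifelse(aln >= 0.9 * len, "WITHIN_RANGE", "WITHIN_RANGE_SHORT_ALIGN")))
}

# map an amino-acid span in a frame translation to 1-based nt coordinates on
# the original contig
.aa_span_to_nt <- function(frame, contig_len, aa_start, aa_end) {
  off <- abs(frame) - 1L
  o_start <- off + 3L * (aa_start - 1L) + 1L
  o_end <- off + 3L * aa_end
  if (frame > 0L) c(o_start, o_end)
  else c(contig_len - o_end + 1L, contig_len - o_start + 1L)
}

#' Translated local search of an ortholog cluster against contigs
#'
#' Each member protein is aligned (Smith-Waterman, BLOSUM62, gap open 11 /
#' extend 1, via Biostrings) against all six frames of every contig.
#' Significance uses the Karlin-Altschul form `E = K * m * n *
#' exp(-lambda * S)` with gapped BLOSUM62 constants (lambda 0.267, K 0.041),
#' where m is the query length and n the summed residue count of all frames
#' searched. A BLAST-style exact `word_size`-mer prescreen skips frames
#' sharing no word with any member (disable with `seed_filter = FALSE`).
#'
#' @param cluster a `kog_cluster` (see [gen_kog_cluster()],
#'   [read_kog_fasta()]).
#' @param contigs named character vector of contig sequences (non-empty).
#' @param evalue_cutoff report alignments with E-value at or below this.
#' @param seed_filter,word_size the exact-word prescreen.
#' @return data frame sorted by descending score: `cluster_id`, `member`,
#'   `contig_id`, `frame`, `score`, `evalue`, `q_start`, `q_end` (query aa),
#'   `s_start_aa`, `s_end_aa` (frame aa), `s_start_nt`, `s_end_nt` (1-based
#'   contig nt), `aligned_length_aa` (query residues spanned),
#'   `percent_identity`.
#' @export
translated_search <- function(cluster, contigs, evalue_cutoff = 1e-6,
                              seed_filter = TRUE, word_size = 5L) {
  if (!length(contigs)) stop("no contigs to search")
  frames <- .frames_table(contigs)
  .translated_search_frames(cluster, frames,
                            search_n = sum(nchar(frames$aa)),
                            contig_len = setNames(nchar(contigs),
                                                  names(contigs)),
                            evalue_cutoff = evalue_cutoff,
                            seed_filter = seed_filter, word_size = word_size)
}

.empty_hits <- function() {
  data.frame(cluster_id = character(), member = character(),
             contig_id = character(), frame = integer(), score = numeric(),
             evalue = numeric(), q_start = integer(), q_end = integer(),
             s_start_aa = integer(), s_end_aa = integer(),
             s_start_nt = integer(), s_end_nt = integer(),
             aligned_length_aa = integer(), percent_identity = numeric(),
             stringsAsFactors = FALSE)
}

.translated_search_frames <- function(cluster, frames, search_n, contig_len,
                                      evalue_cutoff = 1e-6,
                                      seed_filter = TRUE, word_size = 5L) {
  mat <- .blosum62()
  members <- cluster$members
  if (seed_filter) {
    keep <- shares_word_cpp(unname(members), frames$aa, as.integer(word_size))
    frames <- frames[keep, , drop = FALSE]
  }
  if (!nrow(frames)) return(.empty_hits())
  subj <- Biostrings::AAStringSet(frames$aa)
  rows <- vector("list", length(members))
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    # score gate equivalent to the E-value cutoff
    smin <- log(.KA_K * nchar(m) * search_n / evalue_cutoff) / .KA_LAMBDA
    sc <- Biostrings::pairwiseAlignment(subj, Biostrings::AAString(m),
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 11, gapExtension = 1,
                                        scoreOnly = TRUE)
    hit <- which(sc >= smin & nchar(frames$aa) > 0L)
    if (!length(hit)) next
    al <- Biostrings::pairwiseAlignment(subj[hit], Biostrings::AAString(m),
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 11, gapExtension = 1)
    f <- frames[hit, , drop = FALSE]
    nt <- t(vapply(seq_along(hit), function(j)
      .aa_span_to_nt(f$frame[j], contig_len[[f$contig_id[j]]],
                     Biostrings::start(Biostrings::pattern(al))[j],
                     Biostrings::end(Biostrings::pattern(al))[j]),
      integer(2L)))
    qs <- Biostrings::start(Biostrings::subject(al))
    qe <- Biostrings::end(Biostrings::subject(al))
    rows[[mi]] <- data.frame(
      cluster_id = cluster$cluster_id, member = names(members)[mi],
      contig_id = f$contig_id, frame = f$frame,
      score = Biostrings::score(al),
      evalue = .KA_K * nchar(m) * search_n *
        exp(-.KA_LAMBDA * Biostrings::score(al)),
      q_start = qs, q_end = qe,
      s_start_aa = Biostrings::start(Biostrings::pattern(al)),
      s_end_aa = Biostrings::end(Biostrings::pattern(al)),
      s_start_nt = nt[, 1L], s_end_nt = nt[, 2L],
      aligned_length_aa = qe - qs + 1L,
      percent_identity = Biostrings::pid(al),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(.empty_hits())
  out <- out[order(-out$score, -out$percent_identity, out$contig_id,
                   out$member), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the enclosing ORF of a translated alignment
#'
#' In the alignment's frame, scans 5' from the aligned span for the nearest
#' in-frame ATG (failing if an in-frame stop intervenes or the contig ends
#' first), then translates from that Met to the first downstream in-frame
#' stop. Returns `NA` unless both a start and a stop codon are found inside
#' the contig — a coding sequence is only kept when it has both. A premature
#' stop inside the aligned span truncates the protein there, which is what
#' produces the `SHORTER_THAN_ALIGNMENT` class.
#'
#' @param contig_seq the contig's nucleotide sequence.
#' @param frame alignment frame (+1..+3, -1..-3).
#' @param s_start_nt,s_end_nt aligned span, 1-based contig coordinates.
#' @return the extracted protein (starting with M, stop excluded) or
#'   `NA_character_`.
#' @export
extract_cds <- function(contig_seq, frame, s_start_nt, s_end_nt) {
  L <- nchar(contig_seq)
  if (frame > 0L) {
    s <- contig_seq
    o_start <- s_start_nt
  } else {
    s <- revcomp_cpp(contig_seq)
    o_start <- L - s_end_nt + 1L
  }
  off <- abs(frame) - 1L
  codon_at <- function(ci) substr(s, off + 3L * ci + 1L, off + 3L * ci + 3L)
  c0 <- (o_start - 1L - off) %/% 3L
  start_c <- NA_integer_
  for (ci in seq.int(c0, 0L)) {
    cod <- codon_at(ci)
    if (cod == "ATG") { start_c <- ci; break }
    if (cod %in% .STOPS) break
  }
  if (is.na(start_c)) return(NA_character_)
  n_codons <- (L - off) %/% 3L
  end_c <- NA_integer_
  ci <- start_c + 1L
  while (ci < n_codons) {
    if (codon_at(ci) %in% .STOPS) { end_c <- ci; break }
    ci <- ci + 1L
  }
  if (is.na(end_c)) return(NA_character_)
  orf <- substr(s, off + 3L * start_c + 1L, off + 3L * end_c)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(orf), if.fuzzy.codon = "X")))
}

#' Select the best alignment among candidates with an extractable CDS
#'
#' Highest alignment score; ties broken by higher percent identity, then
#' longer aligned length, then lexicographic contig id.
#'
#' @param candidates data frame with columns `score`, `percent_identity`,
#'   `aligned_length_aa`, `contig_id` (non-empty).
#' @return the selected row.
#' @export
select_best <- function(candidates) {
  if (!nrow(candidates)) stop("no candidates")
  ord <- order(-candidates$score, -candidates$percent_identity,
               -candidates$aligned_length_aa, candidates$contig_id)
  candidates[ord[1L], , drop = FALSE]
}

#' Compare an extracted protein against a canonical proteome
#'
#' Best match by global alignment identity; `identical` requires a verbatim
#' full-length match.
#'
#' @param protein an amino-acid string.
#' @param canonical_proteins non-empty named character vector.
#' @return list with `identical`, `n_mismatches`, `best_id`.
#' @export
compare_canonical <- function(protein, canonical_proteins) {
  if (!length(canonical_proteins)) stop("empty canonical set")
  exact <- which(canonical_proteins == protein)
  if (length(exact))
    return(list(identical = TRUE, n_mismatches = 0L,
                best_id = names(canonical_proteins)[exact[1L]]))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(canonical_proteins)),
    Biostrings::AAString(protein), type = "global",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  best <- which.max(Biostrings::pid(al))
  list(identical = FALSE,
       n_mismatches = Biostrings::nmismatch(al)[best],
       best_id = names(canonical_proteins)[best])
}

#' Score an assembly for conserved-gene completeness
#'
#' One record per ortholog cluster: whether any alignment passes the E-value
#' gate (`detected`), the best extracted protein among passing alignments
#' that yield a complete ORF, its five-way size classification, and
#' `full_length` (classification `WITHIN_RANGE`). Optionally compares each
#' extracted protein against a canonical proteome.
#'
#' @param assembly an `assembly` object.
#' @param clusters list of `kog_cluster` objects.
#' @param evalue_cutoff E-value gate for detection (default 1e-6).
#' @param canonical optional named character vector of canonical proteins.
#' @param max_candidates at most this many top-scoring alignments per cluster
#'   are tried for CDS extraction.
#' @param seed_filter,word_size see [translated_search()].
#' @return a `kog_scores` object: list with `hits` (one row per cluster) and
#'   `summary` (`n_detected`, `n_within_length`, `n_full_length`).
#' @export
score_assembly <- function(assembly, clusters, evalue_cutoff = 1e-6,
                           canonical = NULL, max_candidates = 20L,
                           seed_filter = TRUE, word_size = 5L) {
  contigs <- assembly$contigs
  frames <- if (length(contigs)) .frames_table(contigs) else NULL
  search_n <- if (is.null(frames)) 0 else sum(nchar(frames$aa))
  contig_len <- setNames(nchar(contigs), names(contigs))
  recs <- lapply(clusters, function(cl) {
    rec <- data.frame(cluster_id = cl$cluster_id, detected = FALSE,
                      protein = NA_character_, protein_len_aa = NA_integer_,
                      size_class = NA_character_, full_length = FALSE,
                      contig_id = NA_character_, score = NA_real_,
                      evalue = NA_real_, percent_identity = NA_real_,
                      aligned_length_aa = NA_integer_,
                      canonical_identical = NA, canonical_mismatches =
                        NA_integer_, stringsAsFactors = FALSE)
    if (is.null(frames)) return(rec)
    hits <- .translated_search_frames(cl, frames, search_n, contig_len,
                                      evalue_cutoff = evalue_cutoff,
                                      seed_filter = seed_filter,
                                      word_size = word_size)
    if (!nrow(hits)) return(rec)
    rec$detected <- TRUE
    cand <- utils::head(hits, max_candidates)
    cand$protein <- vapply(seq_len(nrow(cand)), function(i)
      extract_cds(contigs[[cand$contig_id[i]]], cand$frame[i],
                  cand$s_start_nt[i], cand$s_end_nt[i]), "")
    cand <- cand[!is.na(cand$protein), , drop = FALSE]
    if (!nrow(cand)) return(rec)
    best <- select_best(cand)
    len <- nchar(best$protein)
    cls <- classify_length(len, best$aligned_length_aa,
                           c(cl$lower_bound_aa, cl$upper_bound_aa))
    rec$protein <- best$protein
    rec$protein_len_aa <- len
    rec$size_class <- cls
    rec$full_length <- cls == "WITHIN_RANGE"
    rec$contig_id <- best$contig_id
    rec$score <- best$score
    rec$evalue <- best$evalue
    rec$percent_identity <- best$percent_identity
    rec$aligned_length_aa <- best$aligned_length_aa
    if (!is.null(canonical)) {
      cc <- compare_canonical(best$protein, canonical)
      rec$canonical_identical <- cc$identical
      rec$canonical_mismatches <- cc$n_mismatches
    }
    rec
  })
  hits <- do.call(rbind, recs)
  rownames(hits) <- NULL
  structure(list(
    hits = hits,
    summary = list(
      n_detected = sum(hits$detected),
      n_within_length = sum(hits$size_class %in%
        c("WITHIN_RANGE", "WITHIN_RANGE_SHORT_ALIGN"), na.rm = TRUE),
      n_full_length = sum(hits$full_length))), class = "kog_scores")
}

#' @export
print.kog_scores <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("kog_scores: %d clusters scored; %d detected, ",
                     "%d within length range, %d full-length\n"),
              nrow(x$hits), s$n_detected, s$n_within_length,
              s$n_full_length))
  invisible(x)
}

#' Saturation table across a depth ladder
#'
#' One row per depth combining [assembly_metrics()] with the completeness
#' summary of [score_assembly()] — the tabular form of the saturation curves
#' of genes detected and genes assembled full-length as a function of read
#' count.
#'
#' @param assemblies list of `assembly` objects, one per depth.
#' @param depths ascending read counts matching `assemblies`.
#' @param clusters list of `kog_cluster` objects.
#' @param evalue_cutoff detection gate.
#' @param ... passed on to [score_assembly()].
#' @return a data frame with the metric columns plus `n_detected`,
#'   `n_within_length`, `n_full_length`.
#' @export
saturation_table <- function(assemblies, depths, clusters,
                             evalue_cutoff = 1e-6, ...) {
  stopifnot(length(assemblies) == length(depths))
  if (any(diff(as.numeric(depths)) <= 0))
    stop("depths must be strictly ascending")
  rows <- lapply(seq_along(depths), function(i) {
    met <- assembly_metrics(assemblies[[i]], depths[i])
    sc <- score_assembly(assemblies[[i]], clusters,
                         evalue_cutoff = evalue_cutoff, ...)$summary
    cbind(met, data.frame(n_detected = sc$n_detected,
                          n_within_length = sc$n_within_length,
                          n_full_length = sc$n_full_length))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write ortholog clusters as FASTA
#'
#' Reference clusters travel as protein FASTA with headers
#' `>clusterID|species`; one cluster groups all records sharing a cluster id,
#' and its full-length size bounds are derived on read with [size_bounds()].
#'
#' @param path FASTA path.
#' @return `read_kog_fasta()`: a named list of `kog_cluster` objects.
#' @export
read_kog_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  cid <- vapply(parts, `[`, "", 1L)
  sp <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "unknown", "")
  out <- lapply(split(seq_along(seqs), cid), function(idx) {
    members <- setNames(unname(seqs[idx]), sp[idx])
    if (length(members) < 2L)
      stop("cluster ", cid[idx[1L]], " has fewer than 2 members")
    b <- size_bounds(nchar(members))
    structure(list(cluster_id = cid[idx[1L]], members = members,
                   lower_bound_aa = b[["lower"]],
                   upper_bound_aa = b[["upper"]]), class = "kog_cluster")
  })
  out[unique(cid)]
}

#' @rdname read_kog_fasta
#' @param clusters list of `kog_cluster` objects.
#' @export
write_kog_fasta <- function(clusters, path) {
  seqs <- do.call(c, unname(lapply(clusters, function(cl)
    setNames(cl$members, paste0(cl$cluster_id, "|", names(cl$members))))))
  write_fasta(seqs, path)
}
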