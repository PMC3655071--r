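## Ground-truth generators: transcriptomes, ortholog clusters, read libraries.
## Everything is deterministic given its seed argument (local RNG state).

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# codons per amino acid, standard genetic code (no stops)
.CODONS <- list(
  A = c("GCT","GCC","GCA","GCG"), R = c("CGT","CGC","CGA","CGG","AGA","AGG"),
  N = c("AAT","AAC"), D = c("GAT","GAC"), C = c("TGT","TGC"),
  Q = c("CAA","CAG"), E = c("GAA","GAG"), G = c("GGT","GGC","GGA","GGG"),
  H = c("CAT","CAC"), I = c("ATT","ATC","ATA"),
  L = c("TTA","TTG","CTT","CTC","CTA","CTG"), K = c("AAA","AAG"),
  M = "ATG", F = c("TTT","TTC"), P = c("CCT","CCC","CCA","CCG"),
  S = c("TCT","TCC","TCA","TCG","AGT","AGC"), T = c("ACT","ACC","ACA","ACG"),
  W = "TGG", Y = c("TAT","TAC"), V = c("GTT","GTC","GTA","GTG"))
.STOPS <- c("TAA", "TAG", "TGA")

# uniform integer draws on [lo, hi]; safe when lo == hi (unlike sample())
.runifint <- function(n, lo, hi) {
  lo + (sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# random nucleotide string with an exact G+C count hit at round(gc * len)
.rand_seq <- function(len, gc) {
  n_gc <- round(gc * len)
  base <- sample(c("A", "T"), len, replace = TRUE)
  if (n_gc > 0L) {
    pos <- sample.int(len, n_gc)
    base[pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  }
  paste(base, collapse = "")
}

#' Generate a ground-truth transcriptome
#'
#' Draws `n_genes` transcripts with lengths uniform over `length_range` and
#' per-transcript GC targets from `Normal(gc[1], gc[2])` (clamped to
#' \[0.02, 0.98\]). Sequences are built with an exact base count at the target
#' so realized GC tracks the target to rounding. Expression weights default
#' to uniform; assign others with [gen_expression()].
#'
#' @param n_genes number of transcripts (>= 1).
#' @param length_range `c(min, max)` transcript length in nt, min >= 3.
#' @param gc `c(mean, sd)` of the per-transcript GC target.
#' @param seed integer seed; same seed, same transcriptome.
#' @return a `transcriptome`: data frame with columns `id`, `sequence`,
#'   `expression_weight`, `gc_target`, `kog_cluster_id`, `cds_start`,
#'   `cds_end`, `cds_strand` (CDS columns `NA` here; see
#'   [gen_kog_transcriptome()]).
#' @export
gen_transcriptome <- function(n_genes, length_range = c(500L, 2500L),
                              gc = c(0.45, 0.05), seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length_range[1L] < 3L) stop("minimum transcript length must be >= 3")
  if (gc[1L] < 0 || gc[1L] > 1) stop("infeasible GC target: must lie in [0, 1]")
  .with_seed(seed, {
    lens <- .runifint(n_genes, length_range[1L], length_range[2L])
    gct <- pmin(0.98, pmax(0.02, rnorm(n_genes, gc[1L], gc[2L])))
    seqs <- vapply(seq_len(n_genes),
                   function(i) .rand_seq(lens[i], gct[i]), "")
    out <- data.frame(id = sprintf("tx%04d", seq_len(n_genes)),
                      sequence = seqs,
                      expression_weight = rep(1 / n_genes, n_genes),
                      gc_target = gct,
                      kog_cluster_id = NA_character_,
                      cds_start = NA_integer_, cds_end = NA_integer_,
                      cds_strand = NA_character_,
                      stringsAsFactors = FALSE)
    class(out) <- c("transcriptome", "data.frame")
    out
  })
}

#' Generate expression weights spanning a dynamic range
#'
#' Log-uniform relative abundances: `10^U(0, orders_of_magnitude)`,
#' normalized to sum to 1. With `orders_of_magnitude = 0` all weights are
#' equal. For `n >= 50` the realized `log10(max/min)` is close to the
#' requested number of orders of magnitude.
#'
#' @param n number of genes (>= 1).
#' @param orders_of_magnitude dynamic range in decades (>= 0).
#' @param seed integer seed.
#' @return numeric weights summing to 1.
#' @export
gen_expression <- function(n, orders_of_magnitude = 3, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (orders_of_magnitude < 0) stop("orders_of_magnitude must be >= 0")
  .with_seed(seed, {
    w <- 10^runif(n, 0, orders_of_magnitude)
    w / sum(w)
  })
}

#' Generate a conserved-ortholog (KOG-style) reference cluster
#'
#' One conserved gene across `n_species` reference species: an ancestral
#' protein (always starting with Met) copied per species with i.i.d.
#' substitutions at `substitution_rate` and terminal truncation/extension
#' implementing length variability. With the default jitter the spread from
#' longest to shortest member averages about 11.8% of the shortest.
#'
#' @param ancestral_protein_length length of the ancestral protein (aa).
#' @param n_species number of member species (>= 2).
#' @param substitution_rate per-site substitution probability in \[0, 1).
#' @param length_jitter target mean (longest - shortest) / shortest.
#' @param seed integer seed.
#' @param cluster_id label for the cluster.
#' @return a `kog_cluster`: list with `cluster_id`, `members` (named
#'   character, one protein per species), `lower_bound_aa`, `upper_bound_aa`
#'   (ratio-based full-length bounds, see [size_bounds()]).
#' @export
gen_kog_cluster <- function(ancestral_protein_length, n_species = 6L,
                            substitution_rate = 0.05, length_jitter = 0.118,
                            seed = 1L, cluster_id = "KOG0001") {
  if (n_species < 2L) stop("n_species must be >= 2")
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)")
  .with_seed(seed, {
    L <- as.integer(ancestral_protein_length)
    anc <- c("M", sample(.AA20, L - 1L, replace = TRUE))
    # uniform jitter of half-width 0.7 * j: expected max-min spread of
    # n draws is width * (n-1)/(n+1), ~= j * L for n = 6
    u <- runif(n_species, -0.7 * length_jitter, 0.7 * length_jitter)
    members <- vapply(seq_len(n_species), function(i) {
      Li <- max(10L, as.integer(round(L * (1 + u[i]))))
      p <- if (Li <= L) anc[seq_len(Li)]
           else c(anc, sample(.AA20, Li - L, replace = TRUE))
      hit <- which(runif(Li) < substitution_rate)
      hit <- setdiff(hit, 1L)  # keep the initiator Met
      for (j in hit) p[j] <- sample(setdiff(.AA20, p[j]), 1L)
      paste(p, collapse = "")
    }, "")
    names(members) <- sprintf("sp%02d", seq_len(n_species))
    b <- size_bounds(nchar(members))
    structure(list(cluster_id = cluster_id, members = members,
                   lower_bound_aa = b[["lower"]],
                   upper_bound_aa = b[["upper"]]),
              class = "kog_cluster")
  })
}

#' @export
print.kog_cluster <- function(x, ...) {
  cat("kog_cluster", x$cluster_id, "-", length(x$members), "members,",
      "lengths", min(nchar(x$members)), "-", max(nchar(x$members)),
      "aa, full-length bounds [", x$lower_bound_aa, ",",
      x$upper_bound_aa, "] aa\n")
  invisible(x)
}

# back-translate a protein into a CDS: ATG ... stop, uniform synonymous codons
.back_translate <- function(protein) {
  aas <- strsplit(protein, "")[[1L]]
  codons <- vapply(aas, function(a) {
    cc <- .CODONS[[a]]
    if (is.null(cc)) stop("cannot back-translate residue ", a)
    cc[sample.int(length(cc), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), sample(.STOPS, 1L))
}

#' Generate a transcriptome carrying conserved-gene coding sequences
#'
#' For each ortholog cluster, back-translates its first member (the "focal
#' species" protein) into a CDS (ATG through stop) and embeds it between
#' random UTRs, then appends `n_extra_genes` plain transcripts with no
#' conserved gene. This is the ground truth used for completeness scoring:
#' every cluster is plantable, so a perfect assembly recovers every CDS
#' full-length.
#'
#' @param clusters list of [gen_kog_cluster()] objects.
#' @param n_extra_genes transcripts without a conserved CDS.
#' @param utr_range `c(min, max)` UTR length in nt (each side).
#' @param gc `c(mean, sd)` GC target for UTRs and extra genes.
#' @param seed integer seed.
#' @return a `transcriptome` data frame (see [gen_transcriptome()]) whose
#'   CDS-bearing rows have `kog_cluster_id` and 1-based `cds_start`/`cds_end`
#'   set.
#' @export
gen_kog_transcriptome <- function(clusters, n_extra_genes = 10L,
                                  utr_range = c(40L, 160L),
                                  gc = c(0.45, 0.05), seed = 1L) {
  .with_seed(seed, {
    rows <- lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      cds <- .back_translate(unname(cl$members[[1L]]))
      u5 <- .rand_seq(.runifint(1L, utr_range[1L], utr_range[2L]),
                      pmin(0.98, pmax(0.02, rnorm(1L, gc[1L], gc[2L]))))
      u3 <- .rand_seq(.runifint(1L, utr_range[1L], utr_range[2L]),
                      pmin(0.98, pmax(0.02, rnorm(1L, gc[1L], gc[2L]))))
      seq <- paste0(u5, cds, u3)
      data.frame(id = sprintf("tx%04d", i), sequence = seq,
                 expression_weight = NA_real_,
                 gc_target = gc_fraction(seq),
                 kog_cluster_id = cl$cluster_id,
                 cds_start = nchar(u5) + 1L,
                 cds_end = nchar(u5) + nchar(cds),
                 cds_strand = "+", stringsAsFactors = FALSE)
    })
    extra <- if (n_extra_genes > 0L) {
      ex <- gen_transcriptome(n_extra_genes, c(500L, 1200L), gc,
                              seed = sample.int(2^30, 1L))
      ex$id <- sprintf("tx%04d", length(clusters) + seq_len(n_extra_genes))
      ex
    } else NULL
    out <- rbind(do.call(rbind, rows), extra)
    out$expression_weight <- 1 / nrow(out)
    rownames(out) <- NULL
    class(out) <- c("transcriptome", "data.frame")
    out
  })
}

#' Simulate a paired-end read library
#'
#' Fragments are drawn from transcripts with probability proportional to
#' expression weight times length; the insert is `Normal(insert_mean,
#' insert_sd)` (clamped to the feasible range), mate 1 reads the fragment
#' start and mate 2 the reverse complement of the fragment end, with the two
#' roles swapped at random (non-strand-specific protocol). Each read is
#' independently assigned an artifact category: `adapter` (read-through: the
#' read 3' end is the adapter sequence, verbatim), `polyt` (a polyT artifact,
#' 97% T), `lowq` (baseline qualities drawn from Normal(20, 3) instead of
#' Normal(38, 2)), or `clean`. Sequencing errors are i.i.d. substitutions at
#' `error_rate` on genomic bases (planted adapter bases are never corrupted,
#' so the filter's recall on planted artifacts is exact).
#'
#' @param transcripts a `transcriptome` data frame.
#' @param n_pairs number of read pairs (> 0).
#' @param read_len read length in nt (<= `insert_mean`).
#' @param insert_mean,insert_sd fragment (insert) length model, nt.
#' @param error_rate per-base substitution probability.
#' @param adapter_seq adapter used for read-through contamination.
#' @param adapter_rate,polyt_rate,lowq_rate per-read artifact probabilities.
#' @param seed integer seed.
#' @return list with `reads` (a [read_set()], mates interleaved) and `truth`
#'   (a `synthetic_truth`: per-read provenance data frame plus the full
#'   parameter list).
#' @export
gen_reads <- function(transcripts, n_pairs, read_len = 100L,
                      insert_mean = 180L, insert_sd = 20L,
                      error_rate = 0.005,
                      adapter_seq = truseq_adapters()[[1L]],
                      adapter_rate = 0, polyt_rate = 0, lowq_rate = 0,
                      seed = 1L) {
  if (n_pairs <= 0L) stop("n_pairs must be > 0")
  if (read_len > insert_mean) stop("read_len must be <= insert_mean")
  rates <- c(adapter_rate, polyt_rate, lowq_rate)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1)
    stop("artifact rates must be in [0, 1] and sum to <= 1")
  .with_seed(seed, {
    tl <- nchar(transcripts$sequence)
    w <- transcripts$expression_weight * tl
    tx <- sample.int(nrow(transcripts), n_pairs, replace = TRUE,
                     prob = w / sum(w))
    ins <- pmin(tl[tx], pmax(read_len, round(rnorm(n_pairs, insert_mean,
                                                   insert_sd))))
    start <- floor(runif(n_pairs) * (tl[tx] - ins + 1)) + 1L
    frag <- substr(transcripts$sequence[tx], start, start + ins - 1L)
    fwd <- substr(frag, 1L, read_len)
    rev <- revcomp_cpp(substr(frag, ins - read_len + 1L, ins))
    flip <- runif(n_pairs) < 0.5
    r1 <- ifelse(flip, rev, fwd)
    r2 <- ifelse(flip, fwd, rev)

    n_reads <- 2L * n_pairs
    seqs <- as.vector(rbind(r1, r2))
    u <- runif(n_reads)
    category <- ifelse(u < adapter_rate, "adapter",
                ifelse(u < adapter_rate + polyt_rate, "polyt",
                ifelse(u < sum(rates), "lowq", "clean")))

    # sequencing errors on genomic bases of clean/lowq reads
    if (error_rate > 0) {
      idx <- which(category %in% c("clean", "lowq"))
      nerr <- rbinom(length(idx), nchar(seqs[idx]), error_rate)
      for (j in which(nerr > 0L)) {
        i <- idx[j]
        b <- strsplit(seqs[i], "")[[1L]]
        pos <- sample.int(length(b), nerr[j])
        b[pos] <- vapply(b[pos], function(x)
          sample(setdiff(c("A","C","G","T"), x), 1L), "")
        seqs[i] <- paste(b, collapse = "")
      }
    }
    # adapter read-through: genomic prefix + adapter verbatim
    ai <- which(category == "adapter")
    if (length(ai)) {
      keep <- max(0L, read_len - nchar(adapter_seq))
      seqs[ai] <- paste0(substr(seqs[ai], 1L, keep),
                         substr(adapter_seq, 1L, read_len))
    }
    # polyT artifact: exactly ceiling(97%) T, remainder non-T
    pi_ <- which(category == "polyt")
    if (length(pi_)) {
      n_other <- read_len - as.integer(ceiling(0.97 * read_len))
      seqs[pi_] <- vapply(seq_along(pi_), function(j) {
        b <- rep("T", read_len)
        if (n_other > 0L)
          b[sample.int(read_len, n_other)] <- sample(c("A","C","G"), n_other,
                                                     replace = TRUE)
        paste(b, collapse = "")
      }, "")
    }
    # qualities
    lens <- nchar(seqs)
    mu <- ifelse(category == "lowq", 20, 38)
    sdq <- ifelse(category == "lowq", 3, 2)
    quals <- vapply(seq_len(n_reads), function(i) {
      q <- pmin(41L, pmax(2L, as.integer(round(rnorm(lens[i], mu[i], sdq[i])))))
      phred_encode(q)
    }, "")

    ids <- rep(sprintf("sim%07d", seq_len(n_pairs)), each = 2L)
    reads <- read_set(ids, seqs, quals,
                      mate = rep(c(1L, 2L), n_pairs),
                      pair = rep(seq_len(n_pairs), each = 2L))
    truth <- data.frame(read_id = ids,
                        mate = rep(c(1L, 2L), n_pairs),
                        transcript_id = rep(transcripts$id[tx], each = 2L),
                        category = category,
                        frag_start = rep(start, each = 2L),
                        insert_len = rep(ins, each = 2L),
                        mate1_is_reverse = rep(flip, each = 2L),
                        stringsAsFactors = FALSE)
    truth <- structure(list(reads = truth,
                            params = list(n_pairs = n_pairs,
                                          read_len = read_len,
                                          insert_mean = insert_mean,
                                          insert_sd = insert_sd,
                                          error_rate = error_rate,
                                          adapter_seq = adapter_seq,
                                          adapter_rate = adapter_rate,
                                          polyt_rate = polyt_rate,
                                          lowq_rate = lowq_rate,
                                          seed = seed)),
                       class = "synthetic_truth")
    list(reads = reads, truth = truth)
  })
}

#' Illumina TruSeq adapter sequences
#'
#' The TruSeq read-1 and read-2 adapters, the default contaminant model for
#' both the simulator and the filter.
#'
#' @return named character vector of length 2.
#' @export
truseq_adapters <- function() {
  c(read1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    read2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' Simulate a complete study: transcriptome, ortholog clusters, reads
#'
#' Convenience wrapper used by the command-line `simulate` subcommand: builds
#' `n_kog` ortholog clusters and a transcriptome in which each cluster's
#' focal protein is planted as a CDS, draws expression weights spanning
#' `orders` decades, simulates `n_pairs` read pairs, and (optionally) writes
#' `<prefix>_1.fastq`, `<prefix>_2.fastq`, `<prefix>_transcripts.fasta`,
#' `<prefix>_kogs.fasta` and `<prefix>_truth.json`.
#'
#' @param n_genes total genes; `n_kog` of them carry conserved CDSs.
#' @param n_kog number of ortholog clusters.
#' @param n_pairs read pairs to simulate.
#' @param read_len,insert_mean read geometry (nt).
#' @param orders expression dynamic range in decades.
#' @param protein_range `c(min, max)` ancestral protein length (aa).
#' @param error_rate,adapter_rate,polyt_rate,lowq_rate see [gen_reads()].
#' @param seed integer seed.
#' @param out_prefix if non-NULL, write the artifact files with this prefix.
#' @return list with `transcripts`, `clusters`, `reads`, `truth`.
#' @export
simulate_library <- function(n_genes = 60L, n_kog = 50L, n_pairs = 10000L,
                             read_len = 100L, insert_mean = 180L,
                             orders = 1, protein_range = c(120L, 280L),
                             error_rate = 0.005, adapter_rate = 0,
                             polyt_rate = 0, lowq_rate = 0,
                             seed = 1L, out_prefix = NULL) {
  if (n_kog > n_genes) stop("n_kog must be <= n_genes")
  clusters <- .with_seed(seed, {
    lens <- .runifint(n_kog, protein_range[1L], protein_range[2L])
    sub_seeds <- sample.int(2^30, n_kog)
    lapply(seq_len(n_kog), function(i)
      gen_kog_cluster(lens[i], seed = sub_seeds[i],
                      cluster_id = sprintf("KOG%04d", i)))
  })
  tx <- gen_kog_transcriptome(clusters, n_extra_genes = n_genes - n_kog,
                              seed = seed + 101L)
  tx$expression_weight <- gen_expression(nrow(tx), orders, seed = seed + 202L)
  sim <- gen_reads(tx, n_pairs, read_len = read_len,
                   insert_mean = insert_mean, error_rate = error_rate,
                   adapter_rate = adapter_rate, polyt_rate = polyt_rate,
                   lowq_rate = lowq_rate, seed = seed + 303L)
  if (!is.null(out_prefix)) {
    write_fastq_pairs(sim$reads, paste0(out_prefix, "_1.fastq"),
                      paste0(out_prefix, "_2.fastq"))
    write_fasta(setNames(tx$sequence, tx$id),
                paste0(out_prefix, "_transcripts.fasta"))
    write_kog_fasta(clusters, paste0(out_prefix, "_kogs.fasta"))
    jsonlite::write_json(list(reads = sim$truth$reads,
                              params = sim$truth$params),
                         paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(transcripts = tx, clusters = clusters, reads = sim$reads,
       truth = sim$truth)
}
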