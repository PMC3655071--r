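# build a contig around a protein: 5' UTR + back-translated CDS + 3' UTR
orf_contig <- function(protein, utr5 = 60L, utr3 = 60L) {
  cds <- depthsat:::.with_seed(nchar(protein),
                               depthsat:::.back_translate(protein))
  paste0(random_dna(utr5), cds, random_dna(utr3))
}

test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGAAATAA")
  expect_equal(fr[["+1"]], "MK*")
  # the reverse frames translate the reverse complement
  s <- "ATGGCCATTGTAATGGGCCGC"
  expect_equal(six_frame_translate(revcomp(s))[["-1"]],
               six_frame_translate(s)[["+1"]])
  # floor arithmetic on a length-10 sequence: 3 / 3 / 2 residues
  fr10 <- six_frame_translate("ACGTACGTAC")
  expect_equal(nchar(fr10[c("+1", "+2", "+3")]),
               c("+1" = 3L, "+2" = 3L, "+3" = 2L))
})

test_that("size bounds extrapolate the two extreme member ratios", {
  b <- size_bounds(c(80, 100, 120, 140))
  expect_equal(b[["lower"]], 64L)       # 80 * 80/100
  expect_equal(b[["upper"]], 164L)      # ceiling(140 * 140/120)
  expect_equal(size_bounds(c(100, 100, 100)), c(lower = 100L, upper = 100L))
  expect_equal(size_bounds(c(100, 120))[["upper"]], 144L)  # 120 * 120/100
  expect_error(size_bounds(90), "two")
  # bounds always bracket the member lengths
  set.seed(40)
  for (rep in 1:50) {
    lens <- sample(50:500, sample(2:8, 1), replace = TRUE)
    b <- size_bounds(lens)
    expect_lte(b[["lower"]], min(lens))
    expect_gte(b[["upper"]], max(lens))
  }
})

test_that("length classification picks exactly one of the five classes", {
  b <- c(64, 150)
  expect_equal(classify_length(100, 95, b), "WITHIN_RANGE")
  expect_equal(classify_length(100, 80, b), "WITHIN_RANGE_SHORT_ALIGN")
  expect_equal(classify_length(160, 150, b), "TOO_LONG")
  expect_equal(classify_length(50, 40, b), "TOO_SHORT")
  expect_equal(classify_length(50, 60, b), "SHORTER_THAN_ALIGNMENT")
  expect_error(classify_length(0, 10, b), "> 0")
})

test_that("alignment scores match the brute-force Smith-Waterman oracle", {
  set.seed(41)
  mat <- blosum62()
  for (rep in 1:12) {
    n <- sample(10:80, 1)
    q <- random_aa(n)
    s <- if (rep %% 2) random_aa(sample(10:80, 1)) else {
      # a homologous subject: mutated copy embedded in noise
      v <- strsplit(q, "")[[1]]
      i <- sample(n, ceiling(n / 5))
      v[i] <- sample(rownames(mat)[1:20], length(i), TRUE)
      paste0(random_aa(6), paste(v, collapse = ""), random_aa(6))
    }
    got <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(q), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(got, sw_gotoh_score(s, q, mat))
  }
})

test_that("translated search finds a planted protein at full identity", {
  set.seed(42)
  cl <- gen_kog_cluster(120, substitution_rate = 0.05, seed = 42)
  contigs <- c(hit = orf_contig(unname(cl$members[[1]])),
               noise = random_dna(400L))
  hits <- translated_search(cl, contigs, evalue_cutoff = 1e-6)
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_equal(top$contig_id, "hit")
  expect_equal(top$percent_identity, 100)
  expect_equal(top$aligned_length_aa, nchar(cl$members[[top$member]]))
  expect_lte(top$evalue, 1e-6)
  expect_false("noise" %in% hits$contig_id)
  # the word prescreen does not change the result here
  expect_equal(translated_search(cl, contigs, seed_filter = FALSE)$score[1],
               top$score)
})

test_that("unrelated sequence stays below the e-value gate", {
  set.seed(43)
  cl <- gen_kog_cluster(150, seed = 43)
  noise <- setNames(vapply(1:20, function(i) random_dna(500L), ""),
                    sprintf("n%02d", 1:20))
  hits <- translated_search(cl, noise, evalue_cutoff = 1e-6,
                            seed_filter = FALSE)
  expect_equal(nrow(hits), 0L)
})

test_that("CDS extraction demands both start and stop codons", {
  set.seed(44)
  prot <- paste0("M", random_aa(80, setdiff(rownames(blosum62())[1:20], "M")))
  cds <- depthsat:::.with_seed(1, depthsat:::.back_translate(prot))
  utr5 <- random_dna(45L)
  contig <- paste0(utr5, cds, random_dna(45L))
  # alignment span: middle of the ORF, on the codon grid
  span0 <- nchar(utr5) + 1L + 30L
  p <- extract_cds(contig, +1L + (nchar(utr5) %% 3L), nchar(utr5) + 31L,
                   nchar(utr5) + 120L)
  expect_equal(p, prot)
  # same ORF on the reverse strand
  rc <- revcomp(contig)
  L <- nchar(contig)
  fr <- -((nchar(utr5) %% 3L) + 1L)
  p_rc <- extract_cds(rc, fr, L - (nchar(utr5) + 120L) + 1L,
                      L - (nchar(utr5) + 31L) + 1L)
  expect_equal(p_rc, prot)
  # ORF truncated before any stop codon: no extraction
  trunc <- substr(contig, 1, nchar(utr5) + nchar(cds) - 10L)
  expect_true(is.na(extract_cds(trunc, +1L + (nchar(utr5) %% 3L),
                                nchar(utr5) + 31L, nchar(utr5) + 120L)))
  # start codon missing upstream of the aligned region: no extraction
  headless <- substr(contig, nchar(utr5) + 7L, nchar(contig))
  expect_true(is.na(extract_cds(headless, +1L, 25L, 114L)))
})

test_that("a premature stop yields a protein shorter than the alignment", {
  set.seed(45)
  prot <- paste0("M", random_aa(99, setdiff(rownames(blosum62())[1:20], "M")))
  cds <- depthsat:::.with_seed(2, depthsat:::.back_translate(prot))
  # insert an in-frame stop at codon 41
  broken <- paste0(substr(cds, 1, 120), "TAA", substr(cds, 124, nchar(cds)))
  contig <- paste0(random_dna(30L), broken, random_dna(30L))
  p <- extract_cds(contig, +1L, 31L + 3L, 31L + 290L)
  expect_equal(nchar(p), 40L)
  expect_equal(p, substr(prot, 1, 40))
})

test_that("best-alignment selection follows the documented tie-breaks", {
  cand <- data.frame(score = c(120, 80, 120, 120),
                     percent_identity = c(98, 99, 95, 98),
                     aligned_length_aa = c(100, 100, 100, 90),
                     contig_id = c("b", "a", "a", "a"),
                     stringsAsFactors = FALSE)
  best <- select_best(cand)
  expect_equal(best$score, 120)
  expect_equal(best$percent_identity, 98)
  expect_equal(best$aligned_length_aa, 100)
  expect_equal(best$contig_id, "b")
  # exhaustive check against an order() oracle on shuffles
  set.seed(46)
  for (rep in 1:10) {
    sh <- cand[sample(nrow(cand)), ]
    ora <- sh[order(-sh$score, -sh$percent_identity, -sh$aligned_length_aa,
                    sh$contig_id), ][1, ]
    expect_equal(select_best(sh)$contig_id, ora$contig_id)
  }
  expect_error(select_best(cand[0, ]), "no candidates")
})

test_that("canonical comparison reports exact and near matches", {
  set.seed(47)
  prot <- paste0("M", random_aa(60))
  canon <- c(p1 = prot, p2 = random_aa(61))
  expect_true(compare_canonical(prot, canon)$identical)
  mut <- prot
  substr(mut, 30, 30) <- if (substr(prot, 30, 30) == "A") "V" else "A"
  cc <- compare_canonical(mut, canon)
  expect_false(cc$identical)
  expect_equal(cc$n_mismatches, 1L)
  expect_equal(cc$best_id, "p1")
  expect_error(compare_canonical(prot, character()), "empty")
})

test_that("assembly scoring counts planted ORFs and respects truncation", {
  set.seed(48)
  clusters <- lapply(1:8, function(i)
    gen_kog_cluster(100 + 10 * i, seed = 100 + i,
                    cluster_id = sprintf("KOG%04d", i)))
  # exact ORFs for the first 4 clusters, noise contigs otherwise
  contigs <- c(
    setNames(vapply(1:4, function(i)
      orf_contig(unname(clusters[[i]]$members[[1]])), ""),
      sprintf("good%d", 1:4)),
    setNames(vapply(1:3, function(i) random_dna(400L), ""),
             sprintf("noise%d", 1:3)))
  sc <- score_assembly(as_assembly(contigs), clusters)
  expect_equal(sc$summary$n_detected, 4L)
  expect_equal(sc$summary$n_full_length, 4L)
  expect_true(all(sc$hits$percent_identity[sc$hits$detected] == 100))
  # an internally truncated ORF is detected but not full-length
  pr <- unname(clusters[[5]]$members[[1]])
  cds <- depthsat:::.with_seed(3, depthsat:::.back_translate(pr))
  broken <- paste0(substr(cds, 1, 90), "TGA", substr(cds, 94, nchar(cds)))
  contigs2 <- c(contigs, trunc5 = paste0(random_dna(50L), broken,
                                         random_dna(50L)))
  sc2 <- score_assembly(as_assembly(contigs2), clusters)
  h5 <- sc2$hits[sc2$hits$cluster_id == "KOG0005", ]
  expect_true(h5$detected)
  expect_false(h5$full_length)
  expect_equal(h5$size_class, "SHORTER_THAN_ALIGNMENT")
  # empty assembly: nothing detected
  sc0 <- score_assembly(as_assembly(setNames(character(), character())),
                        clusters)
  expect_equal(sc0$summary$n_detected, 0L)
})

test_that("completeness counts nest at every depth", {
  set.seed(49)
  clusters <- lapply(1:5, function(i)
    gen_kog_cluster(110, seed = 200 + i, cluster_id = sprintf("K%d", i)))
  mk <- function(n_good) as_assembly(setNames(
    c(vapply(seq_len(n_good), function(i)
      orf_contig(unname(clusters[[i]]$members[[1]])), ""),
      vapply(seq_len(5 - n_good), function(i) random_dna(300L), "")),
    sprintf("c%d", 1:5)))
  assemblies <- list(mk(1), mk(3), mk(5))
  tab <- saturation_table(assemblies, c(1000, 2000, 4000), clusters)
  expect_equal(tab$n_detected, c(1L, 3L, 5L))
  expect_true(all(tab$n_full_length <= tab$n_within_length))
  expect_true(all(tab$n_within_length <= tab$n_detected))
  expect_equal(nrow(tab), 3L)
})

test_that("ortholog clusters round-trip through FASTA", {
  set.seed(50)
  clusters <- lapply(1:3, function(i)
    gen_kog_cluster(80 + i * 20, seed = 300 + i,
                    cluster_id = sprintf("KOG%04d", i)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_kog_fasta(clusters, f)
  back <- read_kog_fasta(f)
  expect_equal(names(back), sprintf("KOG%04d", 1:3))
  for (i in 1:3) {
    expect_equal(back[[i]]$members, clusters[[i]]$members)
    expect_equal(back[[i]]$lower_bound_aa, clusters[[i]]$lower_bound_aa)
  }
})
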