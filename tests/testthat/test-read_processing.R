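test_that("mean Phred uses a strict threshold: exactly 28 passes", {
  expect_equal(mean_phred(c(40L, 40L, 40L)), 40)
  expect_equal(mean_phred(c(20L, 30L)), 25)
  expect_error(mean_phred(integer()), "empty")
  r28 <- read_set("r", "ACGT", phred_encode(rep(28L, 4L)))
  expect_equal(classify_reads(r28, filter_params()), "keep")
  r27 <- read_set("r", "ACGT", phred_encode(c(28L, 28L, 28L, 27L)))
  expect_equal(classify_reads(r27, filter_params()), "low_quality")
})

test_that("classification applies rules in order and flags artifacts", {
  p <- filter_params()
  polyt <- paste(rep("T", 100), collapse = "")
  expect_equal(classify_read(polyt, flat_qual(100)), "low_complexity")
  ad <- paste0(random_dna(40), truseq_adapters()[[1]],
               random_dna(60 - nchar(truseq_adapters()[[1]])))
  expect_equal(classify_read(ad, flat_qual(100)), "adapter")
  set.seed(1)
  expect_equal(classify_read(random_dna(100), flat_qual(100)), "keep")
  # low quality wins over a sequence-rule failure
  expect_equal(classify_read(polyt, flat_qual(100, 10L)), "low_quality")
  # heavy N content counts as low complexity
  nn <- paste0(random_dna(80), paste(rep("N", 20), collapse = ""))
  expect_equal(classify_read(nn, flat_qual(100)), "low_complexity")
})

test_that("read-through adapter prefixes at the 3' end are caught", {
  ad <- truseq_adapters()[[1]]
  # 15 nt of adapter at the read end, one mismatch
  pre <- substr(ad, 1, 15)
  substr(pre, 8, 8) <- ifelse(substr(pre, 8, 8) == "A", "C", "A")
  set.seed(2)
  r <- paste0(random_dna(85), pre)
  expect_equal(classify_read(r, flat_qual(100)), "adapter")
  # 8 nt is below the 12 nt floor: not evidence of read-through
  r2 <- paste0(random_dna(92), substr(ad, 1, 8))
  expect_equal(classify_read(r2, flat_qual(100)), "keep")
})

test_that("pair resolution follows the salvage rule", {
  set.seed(3)
  good <- random_dna(50)
  mk <- function(qual1, qual2) read_set(c("p", "p"),
                                        c(good, random_dna(50)),
                                        c(flat_qual(50, qual1),
                                          flat_qual(50, qual2)),
                                        mate = c(1L, 2L), pair = c(1L, 1L))
  # mixed pair, salvage on: good mate kept as unpaired
  out <- filter_pairs(mk(40L, 10L), filter_params(salvage_singletons = TRUE))
  expect_equal(nrow(out$reads), 1L)
  expect_equal(out$reads$mate, 0L)
  expect_equal(out$report$removed_broken_pair, 0L)
  # mixed pair, salvage off: the good mate is dropped as a broken pair
  out <- filter_pairs(mk(40L, 10L), filter_params(salvage_singletons = FALSE))
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$report$removed_broken_pair, 1L)
  expect_equal(out$report$removed_low_quality, 1L)
  # intact good pair is kept paired
  out <- filter_pairs(mk(40L, 40L), filter_params())
  expect_equal(out$reads$mate, c(1L, 2L))
})

test_that("filter report counts are conserved on arbitrary input", {
  set.seed(4)
  for (rep in 1:5) {
    tx <- gen_transcriptome(3, c(300, 500), seed = rep)
    sim <- gen_reads(tx, 300, error_rate = 0, adapter_rate = 0.1,
                     polyt_rate = 0.1, lowq_rate = 0.2, seed = rep + 50)
    for (salvage in c(TRUE, FALSE)) {
      out <- filter_pairs(sim$reads, filter_params(salvage_singletons = salvage))
      r <- out$report
      expect_equal(r$kept + r$removed_low_quality + r$removed_adapter +
                     r$removed_low_complexity + r$removed_broken_pair,
                   r$total_reads)
      expect_equal(r$kept, nrow(out$reads))
    }
  }
})

test_that("planted artifacts are recalled exactly; clean reads untouched", {
  tx <- gen_transcriptome(5, c(400, 900), seed = 6)
  sim <- gen_reads(tx, 1500, error_rate = 0.005, adapter_rate = 0.08,
                   polyt_rate = 0.08, lowq_rate = 0.08, seed = 7)
  reason <- classify_reads(sim$reads, filter_params())
  truth <- sim$truth$reads$category
  expect_true(all(reason[truth == "adapter"] == "adapter"))
  expect_true(all(reason[truth == "polyt"] == "low_complexity"))
  expect_true(all(reason[truth == "lowq"] == "low_quality"))
  # no clean read is called adapter or low-complexity
  expect_false(any(reason[truth == "clean"] %in%
                     c("adapter", "low_complexity")))
})

test_that("randomization permutes pair units deterministically", {
  tx <- gen_transcriptome(2, c(300, 400), seed = 8)
  rs <- gen_reads(tx, 500, error_rate = 0, seed = 9)$reads
  a <- randomize_order(rs, seed = 5)
  b <- randomize_order(rs, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$pair, randomize_order(rs, seed = 6)$pair))
  expect_setequal(paste(a$id, a$mate), paste(rs$id, rs$mate))
  # mates remain adjacent and ordered within each unit
  expect_true(all(a$mate[c(TRUE, FALSE)] == 1L & a$mate[c(FALSE, TRUE)] == 2L))
})

test_that("nested subsets are prefixes of one another", {
  set.seed(10)
  for (rep in 1:5) {
    rs <- clean_reads(80)
    rs <- randomize_order(rs, seed = rep)
    depths <- sort(sample(5:80, 4))
    subs <- nested_subsets(rs, depths)
    for (i in seq_along(subs)) {
      expect_gte(nrow(subs[[i]]), depths[i])
      if (i > 1)
        expect_identical(subs[[i]][seq_len(nrow(subs[[i - 1]])), ],
                         subs[[i - 1]])
    }
    expect_identical(nested_subsets(rs, nrow(rs))[[1]]$id, rs$id)
  }
  rs <- clean_reads(10)
  expect_error(nested_subsets(rs, c(4, 2)), "ascending")
  expect_error(nested_subsets(rs, 11), "exceeds")
})

test_that("filtering commutes with unit-prefix selection", {
  tx <- gen_transcriptome(3, c(300, 500), seed = 12)
  sim <- gen_reads(tx, 400, error_rate = 0, adapter_rate = 0.1,
                   lowq_rate = 0.2, seed = 13)
  rs <- randomize_order(sim$reads, seed = 14)
  p <- filter_params()
  units <- unique(rs$pair)[1:100]
  prefix <- rs[rs$pair %in% units, , drop = FALSE]
  class(prefix) <- c("read_set", "data.frame")
  a <- filter_pairs(prefix, p)$reads
  whole <- filter_pairs(rs, p)$reads
  b <- whole[whole$pair %in% units, , drop = FALSE]
  expect_equal(a$id, b$id)
  expect_equal(a$seq, b$seq)
  expect_equal(a$mate, b$mate)
})
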