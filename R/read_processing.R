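#' Read filtration parameters
#'
#' Rules applied per read, in fixed order: low quality (mean Phred strictly
#' below `min_mean_phred`), adapter (any configured adapter as exact
#' substring, or a 3' read suffix matching an adapter prefix of >= 12 nt with
#' at most one mismatch), low complexity (dominant base at or above
#' `low_complexity_fraction` of non-N positions, a homopolymer run covering
#' >= `max_homopolymer_fraction` of the read, or more than `max_n_fraction`
#' N). The first failing rule is the recorded rejection reason.
#'
#' @param min_mean_phred reject reads with mean Phred strictly below this.
#' @param adapter_seqs character vector of adapter sequences (may be empty).
#' @param low_complexity_fraction dominant-base fraction threshold, in (0, 1].
#' @param max_homopolymer_fraction homopolymer-run fraction threshold.
#' @param max_n_fraction maximum tolerated fraction of N.
#' @param salvage_singletons keep the good mate of a mixed pair as unpaired
#'   (the rule used for a largest assembly); if `FALSE` only intact good
#'   pairs survive.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_mean_phred = 28,
                          adapter_seqs = truseq_adapters(),
                          low_complexity_fraction = 0.9,
                          max_homopolymer_fraction = 0.8,
                          max_n_fraction = 0.1,
                          salvage_singletons = TRUE) {
  if (min_mean_phred < 0) stop("min_mean_phred must be >= 0")
  if (low_complexity_fraction <= 0 || low_complexity_fraction > 1)
    stop("low_complexity_fraction must be in (0, 1]")
  structure(list(min_mean_phred = min_mean_phred,
                 adapter_seqs = as.character(adapter_seqs),
                 low_complexity_fraction = low_complexity_fraction,
                 max_homopolymer_fraction = max_homopolymer_fraction,
                 max_n_fraction = max_n_fraction,
                 salvage_singletons = isTRUE(salvage_singletons)),
            class = "filter_params")
}

#' Mean Phred score of a read
#'
#' Arithmetic mean of the integer Phred scores. The quality rule rejects a
#' read only when this mean is strictly below the threshold, so a read
#' averaging exactly 28 passes the default filter.
#'
#' @param qualities integer Phred scores, or a single ASCII quality string.
#' @return the mean score.
#' @export
mean_phred <- function(qualities) {
  if (is.character(qualities)) qualities <- phred_decode(qualities)
  if (!length(qualities)) stop("empty quality vector")
  mean(qualities)
}

.mean_phred_vec <- function(quals) {
  vapply(quals, function(q) mean(utf8ToInt(q)), 0) - 33
}

#' Classify reads against the filtration rules
#'
#' @param reads a [read_set()], or `classify_read()` for one sequence/quality.
#' @param params a [filter_params()].
#' @return `classify_reads()`: a character vector over
#'   `keep | low_quality | adapter | low_complexity`, one per read.
#' @export
classify_reads <- function(reads, params = filter_params()) {
  if (!nrow(reads)) return(character())
  reason <- rep("keep", nrow(reads))
  lowq <- .mean_phred_vec(reads$qual) < params$min_mean_phred
  flags <- seq_filter_flags_cpp(reads$seq, params$adapter_seqs,
                                params$low_complexity_fraction,
                                params$max_homopolymer_fraction,
                                params$max_n_fraction)
  reason[flags == 2L] <- "low_complexity"
  reason[flags == 1L] <- "adapter"
  reason[lowq] <- "low_quality"   # checked first: wins over sequence rules
  reason
}

#' @rdname classify_reads
#' @param seq,qual a single read's sequence and ASCII quality string.
#' @export
classify_read <- function(seq, qual, params = filter_params()) {
  classify_reads(read_set("r", seq, qual), params)
}

#' Filter a paired read library
#'
#' Applies [classify_reads()] to every read, then resolves pairs: a pair with
#' both mates passing is kept intact; a mixed pair keeps the good mate as an
#' unpaired read when `salvage_singletons` is set, otherwise drops it (the
#' good mate is counted as `removed_broken_pair`); a pair with both mates
#' failing drops both. Unpaired input reads are kept iff they pass. The
#' report's counts always sum back to the input read count.
#'
#' @param reads a [read_set()].
#' @param params a [filter_params()].
#' @return list with `reads` (the retained [read_set()]) and `report` (a
#'   `filter_report` with fields `total_reads`, `kept`,
#'   `removed_low_quality`, `removed_adapter`, `removed_low_complexity`,
#'   `removed_broken_pair`).
#' @export
filter_pairs <- function(reads, params = filter_params()) {
  reason <- classify_reads(reads, params)
  good <- reason == "keep"
  n_good_in_pair <- stats::ave(as.integer(good), reads$pair, FUN = sum)
  pair_size <- stats::ave(rep(1L, nrow(reads)), reads$pair, FUN = sum)
  keep <- good & (pair_size == 1L | n_good_in_pair == 2L |
                  (n_good_in_pair == 1L & params$salvage_singletons))
  broken <- good & !keep
  out <- reads[keep, , drop = FALSE]
  # good mate salvaged from a mixed pair becomes unpaired
  salv <- stats::ave(rep(1L, nrow(out)), out$pair, FUN = sum) == 1L &
    out$mate != 0L
  out$mate[salv] <- 0L
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  report <- structure(list(
    total_reads = nrow(reads),
    kept = nrow(out),
    removed_low_quality = sum(reason == "low_quality"),
    removed_adapter = sum(reason == "adapter"),
    removed_low_complexity = sum(reason == "low_complexity"),
    removed_broken_pair = sum(broken)), class = "filter_report")
  list(reads = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  rem <- x$total_reads - x$kept
  cat(sprintf("filtered %d reads: kept %d (%.1f%% removed)\n", x$total_reads,
              x$kept, 100 * rem / max(1L, x$total_reads)))
  cat(sprintf("  low quality %d, adapter %d, low complexity %d, broken pair %d\n",
              x$removed_low_quality, x$removed_adapter,
              x$removed_low_complexity, x$removed_broken_pair))
  invisible(x)
}

#' Randomize read order
#'
#' Uniform random permutation of pair units (mates stay adjacent and in mate
#' order), deterministic given the seed. Randomizing the pool before cutting
#' subsets is what makes nested subsamples unbiased draws from the library.
#'
#' @param reads a [read_set()].
#' @param seed integer seed.
#' @return the permuted [read_set()].
#' @export
randomize_order <- function(reads, seed = 1L) {
  units <- unique(reads$pair)
  perm <- .with_seed(seed, sample(units))
  ord <- order(match(reads$pair, perm), reads$mate)
  out <- reads[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Cut nested subsets from a randomized pool
#'
#' Subset i is the shortest prefix of pair units whose read count reaches
#' `depths[i]`, so every subset is a prefix of the next: reads in the 1e6
#' set are all contained in the 5e6 set, and so on. Pairs are never split;
#' a subset may therefore exceed the requested depth by one read when the
#' depth falls inside a pair.
#'
#' @param reads a [read_set()], normally already passed through
#'   [randomize_order()] and [filter_pairs()].
#' @param depths strictly ascending read counts.
#' @return a list of [read_set()]s, one per depth, named by depth.
#' @export
nested_subsets <- function(reads, depths) {
  depths <- as.numeric(depths)
  if (any(diff(depths) <= 0)) stop("depths must be strictly ascending")
  if (max(depths) > nrow(reads))
    stop("depth ", format(max(depths), scientific = FALSE),
         " exceeds available reads by ", max(depths) - nrow(reads))
  # cumulative read count at the end of each pair unit
  unit_of_row <- cumsum(!duplicated(reads$pair))
  reads_by_unit <- cumsum(tabulate(unit_of_row))
  out <- lapply(depths, function(d) {
    n_units <- which(reads_by_unit >= d)[1L]
    sub <- reads[unit_of_row <= n_units, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("read_set", "data.frame")
    sub
  })
  names(out) <- format(depths, scientific = FALSE, trim = TRUE)
  out
}
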