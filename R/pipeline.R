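#' Default pipeline configuration
#'
#' A nested list serializable to/from YAML, covering every stage: simulation
#' (or external FASTQ input), filtration, the depth ladder, assembly and
#' completeness scoring. CLI flags and function arguments override fields;
#' [write_config()]/[read_config()] round-trip the document losslessly.
#'
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @param depths read counts of the ladder (strictly ascending).
#' @param out_dir where [run_pipeline()] writes its artifacts.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, depths = c(4000L, 10000L, 24000L),
                           out_dir = "depthsat_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    depths = as.integer(depths),
    simulate = list(n_genes = 60L, n_kog = 50L, n_pairs = 15000L,
                    read_len = 100L, insert_mean = 180L, orders = 1,
                    error_rate = 0, adapter_rate = 0.02, polyt_rate = 0.01,
                    lowq_rate = 0.05),
    input = list(fastq1 = NULL, fastq2 = NULL, kogs = NULL),
    filter = list(min_mean_phred = 28, low_complexity_fraction = 0.9,
                  salvage_singletons = FALSE),
    assembly = list(k = 21L, coverage_cutoff = 3L, min_contig_length = 100L),
    evalue_cutoff = 1e-6), class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

.stage_log <- function(stage, ...) {
  message(sprintf("[depthsat] %-10s %s", stage, sprintf(...)))
}

#' Run the full saturation pipeline
#'
#' simulate (or load) -> randomize -> filter -> nested subsets -> assemble ->
#' metrics -> completeness scoring -> saturation table, with every stage's
#' output written to `out_dir` before the next starts and a manifest
#' (seed, parameters, file checksums) at the end. Reruns with the same
#' configuration reproduce byte-identical tables.
#'
#' @param config a `run_config` (see [default_config()]); alternatively the
#'   path to a YAML config document.
#' @return the saturation table (invisibly); artifacts on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # --- input: simulate, or load external FASTQ + ortholog clusters
  if (!is.null(config$input$fastq1)) {
    reads <- if (!is.null(config$input$fastq2))
      read_fastq_pairs(config$input$fastq1, config$input$fastq2)
    else read_fastq(config$input$fastq1)
    clusters <- read_kog_fasta(config$input$kogs)
    .stage_log("load", "%d reads, %d clusters", nrow(reads), length(clusters))
  } else {
    sim <- do.call(simulate_library,
                   c(config$simulate, list(seed = config$seed,
                                           out_prefix = out("sim"))))
    reads <- sim$reads
    clusters <- sim$clusters
    .stage_log("simulate", "%d genes (%d with conserved CDS), %d read pairs",
               config$simulate$n_genes, config$simulate$n_kog,
               config$simulate$n_pairs)
  }

  # --- randomize, filter, cut the ladder
  reads <- randomize_order(reads, seed = config$seed + 17L)
  fp <- do.call(filter_params, config$filter)
  flt <- filter_pairs(reads, fp)
  .stage_log("filter", "kept %d of %d reads (lowq %d, adapter %d, lowc %d, broken %d)",
             flt$report$kept, flt$report$total_reads,
             flt$report$removed_low_quality, flt$report$removed_adapter,
             flt$report$removed_low_complexity,
             flt$report$removed_broken_pair)
  write_tsv(as.data.frame(unclass(flt$report)), out("filter_report.tsv"))
  depths <- sort(unique(as.numeric(config$depths)))
  if (max(depths) > nrow(flt$reads))
    stop("subsample stage: depth ", format(max(depths), scientific = FALSE),
         " exceeds the filtered pool of ", nrow(flt$reads), " reads")
  subsets <- nested_subsets(flt$reads, depths)
  .stage_log("subsample", "depth ladder: %s reads",
             paste(names(subsets), collapse = ", "))

  # --- assemble each subset and score it
  ap <- do.call(assembly_params, config$assembly)
  assemblies <- lapply(seq_along(subsets), function(i) {
    a <- assemble(subsets[[i]], ap)
    write_fasta(a$contigs, out(sprintf("contigs_%s.fasta", names(subsets)[i])))
    write_tsv(data.frame(contig_id = names(a$contigs),
                         locus = unname(a$locus)),
              out(sprintf("loci_%s.tsv", names(subsets)[i])))
    .stage_log("assemble", "depth %s: %d contigs in %d loci",
               names(subsets)[i], length(a$contigs),
               length(unique(a$locus)))
    a
  })
  tab <- saturation_table(assemblies, depths, clusters,
                          evalue_cutoff = config$evalue_cutoff)
  write_tsv(.format_saturation(tab), out("saturation.tsv"))
  .stage_log("saturate", "full-length at top depth: %d of %d clusters",
             tab$n_full_length[nrow(tab)], length(clusters))

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(seed = config$seed, depths = depths,
                   config = unclass(config),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(tab)
}

# fixed-precision TSV rendering (GC as percent with 2 decimals)
.format_saturation <- function(tab) {
  tab$gc_percent <- sprintf("%.2f", tab$gc_percent)
  for (col in c("mean_bp", "loci_per_million_reads",
                "transcripts_per_million_reads", "transcripts_per_locus"))
    tab[[col]] <- sprintf("%.3f", tab[[col]])
  tab
}
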