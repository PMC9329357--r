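#' Run the full contamination-monitoring pipeline
#'
#' Orchestrates curation, contaminant identification, in-silico
#' decontamination and the descriptive summaries as one deterministic run:
#' curate (domain-unclassified, non-prokaryotic, singleton filters) ->
#' identify contaminants from the background controls -> decontaminate
#' under the chosen strategy -> summarise (contaminant load, PC/DC Venn
#' partition, taxonomic composition). Every number in the report is
#' recomputable from the emitted stage outputs.
#'
#' @param counts An [otu_tbl()] or a path to a count table readable by
#'   [read_count_table()].
#' @param taxonomy A [taxonomy_tbl()] or a path for [read_taxonomy()].
#' @param samples A [sample_sheet()] or a path for [read_sample_sheet()].
#' @param min_reads Detection threshold for presence calls.
#' @param strategy Decontamination strategy, see [decontaminate()].
#' @param strategy_args Named list of strategy parameters (`threshold`,
#'   `top_k`).
#' @param min_domain_identity,remove_singletons Curation parameters.
#' @param rank,others_threshold Composition parameters, see
#'   [aggregate_taxa()].
#' @param output_dir If non-`NULL`, stage outputs are written there:
#'   `curated.tsv`, `cleaned.tsv`, `catalog.json`, `report.json`,
#'   `composition.tsv`, `relative_abundance.tsv`.
#' @return A `run_report` list: `config` (all defaults echoed for
#'   auditability), `curation` ledger, `catalog`, `overlap`, `decontam`
#'   result, `load`, `venn`, `composition`, and `files` (paths written).
#' @examples
#' rep <- run_pipeline(seaice_counts(), seaice_taxonomy(), seaice_samples())
#' rep$catalog
#' @export
run_pipeline <- function(counts, taxonomy, samples,
                         min_reads = 1L,
                         strategy = "conservative",
                         strategy_args = list(),
                         min_domain_identity = 0.70,
                         remove_singletons = TRUE,
                         rank = "genus",
                         others_threshold = 0.5,
                         output_dir = NULL) {
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  counts <- as_otu_tbl(counts)
  taxonomy <- taxonomy_tbl(taxonomy)
  samples <- sample_sheet(samples)

  curated <- curate(counts, taxonomy,
                    min_domain_identity = min_domain_identity,
                    remove_singletons = remove_singletons)
  ledger <- curation_ledger(curated)
  catalog <- identify_contaminants(curated, samples, min_reads = min_reads)
  overlap <- environmental_overlap(catalog, curated, samples)
  res <- rlang::exec(decontaminate, curated, catalog, samples,
                     strategy = strategy, !!!strategy_args)
  ra <- relative_abundance(curated)
  load <- contaminant_load(ra, catalog, samples)
  venn <- venn_partition(list(PC = catalog$pc_set, DC = catalog$dc_set))
  composition <- aggregate_taxa(ra, taxonomy, rank = rank,
                                others_threshold = others_threshold)

  config <- list(
    tool = "cryoclean",
    version = as.character(utils::packageVersion("cryoclean")),
    min_reads = min_reads, strategy = strategy,
    strategy_args = strategy_args,
    min_domain_identity = min_domain_identity,
    remove_singletons = remove_singletons,
    rank = rank, others_threshold = others_threshold
  )
  report <- structure(
    list(
      config = config,
      curation = ledger,
      catalog = catalog,
      overlap = overlap,
      decontam = res,
      load = load,
      venn = venn,
      composition = composition,
      cleaned = res$cleaned,
      files = character()
    ),
    class = "run_report"
  )
  if (!is.null(output_dir)) {
    report$files <- write_run_report(report, curated, ra, output_dir)
  }
  report
}

write_run_report <- function(report, curated, ra, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_count_table(curated, p("curated.tsv"))
  write_count_table(report$cleaned, p("cleaned.tsv"))
  readr::write_tsv(tibble::as_tibble(ra), p("relative_abundance.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$composition, p("composition.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      contaminant_otu_ids = report$catalog$contaminant_otu_ids,
      provenance = as.list(report$catalog$provenance),
      pc_set = report$catalog$pc_set,
      dc_set = report$catalog$dc_set,
      pc_minus_dc_set = report$catalog$pc_minus_dc_set,
      min_reads = report$catalog$min_reads
    ),
    p("catalog.json"), auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(report_numbers(report), p("report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  vapply(c("curated.tsv", "cleaned.tsv", "relative_abundance.tsv",
           "composition.tsv", "catalog.json", "report.json"),
         p, character(1))
}

report_numbers <- function(report) {
  list(
    schema = "cryoclean-report/1",
    config = report$config,
    curation = as.list(glance(report$curation)),
    catalog = as.list(glance(report$catalog)),
    overlap = as.list(glance(report$overlap)),
    decontamination = as.list(glance(report$decontam)),
    contaminant_load = as.list(glance(report$load)),
    venn_regions = stats::setNames(as.list(report$venn$regions$size),
                                   report$venn$regions$region)
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> cryoclean ", x$config$version, "\n", sep = "")
  g <- glance(x$curation)
  cat("  curation: ", g$otus_before, " -> ", g$otus_after, " OTUs (",
      g$reads_removed, " reads removed)\n", sep = "")
  print(x$catalog)
  print(x$overlap)
  print(x$decontam)
  print(x$load)
  invisible(x)
}
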