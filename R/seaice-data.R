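#' Bundled example dataset: a low-biomass sea-ice survey with two background
#' controls
#'
#' A small worked dataset from a coastal first-year sea-ice contamination
#' survey: 16S rRNA amplicon read counts for the 13 contaminant OTUs that
#' were detected in at least one of two background controls -- a processing
#' control (PC, an artificial sterile ice core handled and filtered
#' alongside the samples) and a DNA-extraction control (DC, a blank filter
#' carried through extraction) -- across two environmental ice cores, three
#' interface-water samples and the two controls.
#'
#' `seaice_counts()` returns the 13 x 7 read-count table; `seaice_taxonomy()`
#' the matching lineages, closest type strains and match scores (classifier
#' confidences are not reported per OTU in the source survey and are `NA`;
#' every genus shown passed the 70% convention); `seaice_samples()` the
#' sample sheet; `seaice_contaminant_abundance()` the published per-sample
#' relative abundances (%) of the same 13 OTUs within the full curated
#' environmental dataset (whose per-sample totals are much larger than the
#' contaminant reads alone); `seaice_dataset_summary()` the headline sizes of
#' the full curated dataset the survey reports (2331 prokaryotic OTUs,
#' 134,230 reads).
#'
#' The same tables are shipped as plain TSV under
#' `system.file("extdata", package = "cryoclean")`.
#'
#' @return Tibbles as described; `seaice_counts()` is an [otu_tbl()].
#' @examples
#' identify_contaminants(seaice_counts(), seaice_samples())
#' @export
seaice_counts <- function() {
  otu_tbl(tibble::tribble(
    ~otu_id,    ~Ice_1, ~Ice_2, ~Water_1, ~Water_2, ~Water_3,   ~PC,   ~DC,
    "OTU_4",        0L,     2L,       0L,       0L,       0L, 6088L, 8506L,
    "OTU_5",        5L,    10L,       0L,       0L,       0L, 9522L, 3770L,
    "OTU_19",       7L,     4L,       1L,       2L,       4L, 1174L, 2122L,
    "OTU_22",       0L,     0L,       0L,       0L,       0L, 3169L,    0L,
    "OTU_25",       2L,     0L,      14L,      46L,      57L, 2771L,    0L,
    "OTU_36",       0L,     0L,       0L,       0L,       2L,    0L, 2165L,
    "OTU_63",       0L,     0L,       0L,       0L,       0L,  310L, 1004L,
    "OTU_70",       0L,     0L,       0L,       0L,       0L, 1170L,    0L,
    "OTU_98",       0L,     0L,       0L,       0L,       2L,    0L,  728L,
    "OTU_103",      0L,     0L,       0L,       0L,       0L,    0L,  141L,
    "OTU_167",      0L,     0L,       0L,       0L,       0L,  269L,    0L,
    "OTU_209",      0L,     0L,       0L,       0L,       0L,   12L,    0L,
    "OTU_1153",     5L,    19L,      15L,      41L,      89L,  131L,    0L
  ))
}

#' @rdname seaice_counts
#' @export
seaice_taxonomy <- function() {
  taxonomy_tbl(tibble::tribble(
    ~otu_id, ~phylum, ~class, ~order, ~family, ~genus, ~type_strain, ~type_strain_score,
    "OTU_4", "Proteobacteria", "Gammaproteobacteria", "Xanthomonadales", "Xanthomonadaceae", "Stenotrophomonas",
      "Stenotrophomonas maltophilia (T); ATCC 19867; AB021405", 0.918,
    "OTU_5", "Actinobacteria", "Actinobacteria", "Corynebacteriales", "Corynebacteriaceae", "Corynebacterium",
      "Corynebacterium tuberculostearicum (T); CIP 107291; AJ438050", 0.966,
    "OTU_19", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas",
      "Pseudomonas proteolytica (T); CMS 64; AJ537603", 0.954,
    "OTU_22", "Campylobacterota", "Campylobacteria", "Campylobacterales", "Sulfurospirillaceae", "Sulfurospirillum",
      "Sulfurospirillum alkalitolerans (T); HTRB-L1; GQ863490", 0.742,
    "OTU_25", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Acinetobacter",
      "Acinetobacter guillouiae (T); DSM 590; X81659", 0.962,
    "OTU_36", "Proteobacteria", "Alphaproteobacteria", "Caulobacterales", "Hyphomonadaceae", "Asprobacter",
      "Asprobacter aquaticus (T); DRW22-8; KF056993", 0.947,
    "OTU_63", "Proteobacteria", "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae", "Escherichia/Shigella",
      "Shigella sonnei (T); CECT 4887; FR870445", 0.977,
    "OTU_70", "Bacteroidota", "Chitinophagia", "Chitinophagales", "Chitinophagaceae", NA,
      "Ferruginibacter alkalilentus (T); HU1-GD23; FJ177530", 0.811,
    "OTU_98", "Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Burkholderia",
      "Burkholderia stabilis (T); LMG 14294; AF097533", 0.954,
    "OTU_103", "Campylobacterota", "Campylobacteria", "Campylobacterales", "Sulfurimonadaceae", "Sulfurimonas",
      "Sulfurimonas denitrificans (T); DSM 1251; CP000153", 0.865,
    "OTU_167", "Acidobacteriota", "Blastocatellia", "Blastocatellales", "Blastocatellaceae", "Aridibacter",
      "Aridibacter famidurans (T); A22_HD_4H; KF245634", 0.918,
    "OTU_209", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Acinetobacter",
      "Acinetobacter radioresistens (T); DSM 6976; X81666", 1.000,
    "OTU_1153", "Campylobacterota", "Campylobacteria", "Campylobacterales", "Sulfurospirillaceae", "Sulfurospirillum",
      "Sulfurospirillum alkalitolerans (T); HTRB-L1; GQ863490", 0.743
  ) |>
    dplyr::mutate(domain = "Bacteria", organelle_flag = "none"))
}

#' @rdname seaice_counts
#' @export
seaice_samples <- function() {
  sample_sheet(tibble::tribble(
    ~sample_id, ~role,                 ~replicate_group,
    "Ice_1",    "environmental_ice",   "ice",
    "Ice_2",    "environmental_ice",   "ice",
    "Water_1",  "environmental_water", "water",
    "Water_2",  "environmental_water", "water",
    "Water_3",  "environmental_water", "water",
    "PC",       "processing_control",  "processing_control",
    "DC",       "extraction_control",  "extraction_control"
  ))
}

#' @rdname seaice_counts
#' @export
seaice_contaminant_abundance <- function() {
  tibble::tribble(
    ~otu_id,    ~Ice_1, ~Ice_2, ~Water_1, ~Water_2, ~Water_3,
    "OTU_4",      0,     0.02,    0,        0,        0,
    "OTU_5",      0.07,  0.09,    0,        0,        0,
    "OTU_19",     0.09,  0.04,    0.004,    0.009,    0.02,
    "OTU_22",     0,     0,       0,        0,        0,
    "OTU_25",     0.03,  0,       0.06,     0.20,     0.2,
    "OTU_36",     0,     0,       0,        0,        0.008,
    "OTU_63",     0,     0,       0,        0,        0,
    "OTU_70",     0,     0,       0,        0,        0,
    "OTU_98",     0,     0,       0,        0,        0.008,
    "OTU_103",    0,     0,       0,        0,        0,
    "OTU_167",    0,     0,       0,        0,        0,
    "OTU_209",    0,     0,       0,        0,        0,
    "OTU_1153",   0.07,  0.17,    0.06,     0.18,     0.35
  )
}

#' @rdname seaice_counts
#' @export
seaice_dataset_summary <- function() {
  tibble::tibble(n_prokaryotic_otus = 2331L, n_reads = 134230L,
                 n_contaminant_otus = 13L)
}

#' Bundled bioburden measurements for the sea-ice survey
#'
#' Culture counts, flow-cytometry cell counts and fluorometric DNA
#' quantification for the same survey. `seaice_cfu()` holds the 30-day R2A
#' plate time series (colonies newly counted every 5 days, CFU/mL, already
#' scaled to natural units from the published x 10^2 values); the water
#' day-5 dispersion could not be read unambiguously from the source table
#' and is marked untrusted. `seaice_cells()` holds cells/mL (x 10^4 scaled
#' out); the processing-control count is printed without dispersion.
#' `seaice_dna()` holds DNA concentrations (ng/uL) with below-detection
#' flags (fluorometric detection limit 0.01 ng/uL, i.e. 10 pg/uL).
#'
#' @return Tibbles, one row per observation.
#' @examples
#' cells <- seaice_cells()
#' control_fraction(cells$cells_per_ml[cells$sample_group == "processing_control"],
#'                  cells$cells_per_ml[cells$sample_group == "water"])
#' @export
seaice_cfu <- function() {
  tibble::tribble(
    ~sample_group,        ~day, ~cfu_per_ml, ~dispersion, ~untrusted,
    "water",                 5L,      40000,        100,  TRUE,
    "water",                10L,       3000,        100,  FALSE,
    "water",                15L,       5000,        100,  FALSE,
    "water",                20L,       2000,        100,  FALSE,
    "water",                25L,       3000,        100,  FALSE,
    "water",                30L,       1000,        300,  FALSE,
    "ice",                   5L,         60,          0,  FALSE,
    "ice",                  10L,        300,         10,  FALSE,
    "ice",                  15L,        300,         70,  FALSE,
    "ice",                  20L,        200,         40,  FALSE,
    "ice",                  25L,        200,         60,  FALSE,
    "ice",                  30L,          0,          0,  FALSE,
    "processing_control",    5L,          0,          0,  FALSE,
    "processing_control",   10L,          0,          0,  FALSE,
    "processing_control",   15L,          0,          0,  FALSE,
    "processing_control",   20L,          0,          0,  FALSE,
    "processing_control",   25L,          0,          0,  FALSE,
    "processing_control",   30L,          0,          0,  FALSE
  )
}

#' @rdname seaice_cfu
#' @export
seaice_cells <- function() {
  tibble::tribble(
    ~sample_group,        ~cells_per_ml, ~dispersion,
    "water",                     360000,       40000,
    "ice",                        34000,       10000,
    "processing_control",          3000,          NA
  )
}

#' @rdname seaice_cfu
#' @export
seaice_dna <- function() {
  tibble::tribble(
    ~sample_id, ~dna_ng_per_ul, ~dispersion, ~below_detection,
    "Ice_1",               0.9,         0.1,  FALSE,
    "Ice_2",               0.4,         0.0,  FALSE,
    "Water_1",             0.9,         0.1,  FALSE,
    "Water_2",             1.1,         0.0,  FALSE,
    "Water_3",             0.1,         0.1,  FALSE,
    "PC",                   NA,          NA,  TRUE,
    "DC",                   NA,          NA,  TRUE
  )
}
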