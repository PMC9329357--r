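#' Read and write OTU count tables
#'
#' The native text format is UTF-8 TSV with `#` comment lines ignored, a
#' header row of sample ids, OTUs as rows and an `otu_id` first column --
#' the orientation in which contaminant tables are usually printed. A dense
#' BIOM-style JSON dialect is available behind `dialect = "biom_json"`
#' (read and written with the biomformat package).
#'
#' Missing cells are an error, never a silent zero: a truncated row fails
#' validation with the offending coordinate.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"biom_json"`.
#' @return `read_count_table()` returns a validated [otu_tbl()] with row and
#'   column order preserved from the file; `write_count_table()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_count_table(seaice_counts(), f)
#' identical(read_count_table(f), seaice_counts())
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_format(paste0("file not found: ", path))
  }
  if (dialect == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    out <- tibble::as_tibble(m, rownames = "otu_id")
    return(otu_tbl(out))
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort_format(paste0(
      "ragged or malformed row in ", path, " (line ", prob$row[1] + 1L, ")."
    ))
  }
  if (ncol(raw) < 1L) abort_format(paste0("no columns in ", path))
  names(raw)[1] <- "otu_id"
  for (s in names(raw)[-1]) {
    v <- raw[[s]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad)) {
      abort_format(paste0(
        "non-numeric count at otu `", raw$otu_id[bad[1]], "`, sample `", s, "`."
      ))
    }
    raw[[s]] <- num
  }
  otu_tbl(raw)
}

#' @rdname read_count_table
#' @param x An [otu_tbl()] (or coercible data frame).
#' @export
write_count_table <- function(x, path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  x <- as_otu_tbl(x)
  if (dialect == "biom_json") {
    b <- biomformat::make_biom(counts_matrix(x))
    biomformat::write_biom(b, path)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}

taxonomy_ranks <- c("domain", "phylum", "class", "order", "family", "genus")
organelle_levels <- c("none", "chloroplast", "mitochondria")

#' Taxonomy tables
#'
#' One row per OTU with ranked lineage labels (`domain` ... `genus`; missing
#' ranks are `NA`, never empty strings), the classifier confidence as a
#' fraction in \[0, 1\] (amplicon convention: assignments below 0.70 are
#' treated as unclassified downstream), an optional closest-type-strain name
#' and match score, and an organelle flag (`none`, `chloroplast`,
#' `mitochondria`).
#'
#' @param x A data frame with at least `otu_id`; recognised further columns
#'   are the six ranks, `confidence`, `type_strain`, `type_strain_score`,
#'   `organelle_flag`. Missing columns are added as `NA`
#'   (`organelle_flag` defaults to `"none"`).
#' @return A validated taxonomy tibble.
#' @export
taxonomy_tbl <- function(x) {
  if (!is.data.frame(x) || !"otu_id" %in% names(x)) {
    abort_format("taxonomy must be a data frame with an `otu_id` column.")
  }
  x <- tibble::as_tibble(x)
  x$otu_id <- as.character(x$otu_id)
  if (anyDuplicated(x$otu_id)) {
    abort_format("duplicate otu_id in taxonomy.")
  }
  for (col in c(taxonomy_ranks, "type_strain")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
    x[[col]] <- as.character(x[[col]])
    x[[col]][!is.na(x[[col]]) & x[[col]] == ""] <- NA_character_
  }
  for (col in c("confidence", "type_strain_score")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
    v <- x[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v) & v != "")) {
        abort_format(paste0("unparseable `", col, "` value in taxonomy."))
      }
      v <- num
    }
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort_format(paste0("`", col, "` must lie in [0, 1] (use `confidence = \"percent\"` when reading percent files)."))
    }
    x[[col]] <- as.numeric(v)
  }
  if (!"organelle_flag" %in% names(x)) x$organelle_flag <- "none"
  x$organelle_flag <- as.character(x$organelle_flag)
  x$organelle_flag[is.na(x$organelle_flag) | x$organelle_flag == ""] <- "none"
  bad <- setdiff(unique(x$organelle_flag), organelle_levels)
  if (length(bad)) {
    abort_format(paste0(
      "unknown organelle_flag `", bad[1], "`; allowed: ",
      paste(organelle_levels, collapse = ", ")
    ))
  }
  x[, c("otu_id", taxonomy_ranks, "confidence", "type_strain",
        "type_strain_score", "organelle_flag")]
}

#' @rdname taxonomy_tbl
#' @param path File path to a TSV with columns `otu_id`, the six ranks,
#'   `confidence`, `type_strain`, `type_strain_score`, `organelle_flag`
#'   (missing columns tolerated).
#' @param confidence Whether `confidence`/`type_strain_score` in the file
#'   are fractions in \[0, 1\] or percentages in \[0, 100\].
#' @param table Optional companion [otu_tbl()]; taxonomy rows for OTUs not
#'   in the table trigger a warning (the taxonomy may be a superset), never
#'   an error.
#' @export
read_taxonomy <- function(path, confidence = c("fraction", "percent"),
                          table = NULL) {
  confidence <- match.arg(confidence)
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in c("confidence", "type_strain_score")) {
    if (col %in% names(raw)) {
      num <- suppressWarnings(as.numeric(raw[[col]]))
      if (any(is.na(num) & !is.na(raw[[col]]) & raw[[col]] != "")) {
        abort_format(paste0("unparseable `", col, "` in ", path))
      }
      if (confidence == "percent") num <- num / 100
      raw[[col]] <- num
    }
  }
  out <- taxonomy_tbl(raw)
  if (!is.null(table)) {
    extra <- setdiff(out$otu_id, otu_ids(table))
    if (length(extra)) {
      rlang::warn(paste0(
        length(extra), " taxonomy OTU(s) absent from the count table ",
        "(taxonomy may be a superset), e.g. ", extra[1]
      ))
    }
  }
  out
}

#' @rdname taxonomy_tbl
#' @export
write_taxonomy <- function(x, path) {
  readr::write_tsv(taxonomy_tbl(x), path, progress = FALSE)
  invisible(path)
}

sample_roles <- c("environmental_ice", "environmental_water",
                  "processing_control", "extraction_control")

#' Sample sheets
#'
#' One row per sample with its `role` (one of `environmental_ice`,
#' `environmental_water`, `processing_control`, `extraction_control`) and a
#' `replicate_group` label used for pooling (defaults to the role when
#' absent). A sheet with no control samples is valid at read time;
#' [identify_contaminants()] refuses it later.
#'
#' @param x A data frame with columns `sample_id`, `role` and optionally
#'   `replicate_group`.
#' @return A validated sample-sheet tibble.
#' @export
sample_sheet <- function(x) {
  if (!is.data.frame(x) || !all(c("sample_id", "role") %in% names(x))) {
    abort_format("sample sheet needs `sample_id` and `role` columns.")
  }
  x <- tibble::as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort_format(paste0("duplicate sample row: ", paste(dup, collapse = ", ")))
  }
  x$role <- as.character(x$role)
  bad <- setdiff(unique(x$role), sample_roles)
  if (length(bad)) {
    abort_format(paste0(
      "unknown role `", bad[1], "`; allowed: ",
      paste(sample_roles, collapse = ", ")
    ))
  }
  if (!"replicate_group" %in% names(x)) x$replicate_group <- NA_character_
  x$replicate_group <- as.character(x$replicate_group)
  miss <- is.na(x$replicate_group) | x$replicate_group == ""
  x$replicate_group[miss] <- x$role[miss]
  x[, c("sample_id", "role", "replicate_group")]
}

#' @rdname sample_sheet
#' @param path File path to a TSV with columns `sample_id`, `role`,
#'   `replicate_group`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  sample_sheet(raw)
}

#' @rdname sample_sheet
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(sample_sheet(x), path, progress = FALSE)
  invisible(path)
}

check_sheet_matches <- function(table, sheet) {
  sheet <- sample_sheet(sheet)
  ids <- sample_ids(table)
  missing <- setdiff(ids, sheet$sample_id)
  if (length(missing)) {
    abort_format(paste0(
      "sample(s) in count table missing from sample sheet: ",
      paste(missing, collapse = ", ")
    ))
  }
  sheet[match(ids, sheet$sample_id), , drop = FALSE]
}

samples_with_role <- function(sheet, roles) {
  sheet$sample_id[sheet$role %in% roles]
}

control_roles <- c("processing_control", "extraction_control")
env_roles <- c("environmental_ice", "environmental_water")
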