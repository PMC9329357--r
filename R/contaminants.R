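#' Call presence/absence from read counts
#'
#' Detection in an amplicon survey is operationalised as "at least
#' `min_reads` reads": the default of 1 equates detection with any
#' sequenced read, the convention under which every control-detected OTU
#' counts as a contaminant. Raising `min_reads` guards against index
#' hopping and other low-level noise; presence calls are monotone in it.
#'
#' @param x An [otu_tbl()] (or coercible data frame).
#' @param min_reads Positive integer detection threshold (reads).
#' @return A tibble with `otu_id` plus one logical column per sample, with
#'   the threshold recorded in the `min_reads` attribute.
#' @examples
#' call_presence(seaice_counts(), min_reads = 5)
#' @export
call_presence <- function(x, min_reads = 1L) {
  x <- as_otu_tbl(x)
  min_reads <- check_min_reads(min_reads)
  out <- x
  for (s in sample_ids(x)) out[[s]] <- x[[s]] >= min_reads
  out <- tibble::as_tibble(out)
  attr(out, "min_reads") <- min_reads
  out
}

check_min_reads <- function(min_reads) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L || is.na(min_reads) ||
      min_reads < 1 || min_reads != trunc(min_reads)) {
    rlang::abort("`min_reads` must be a positive integer.",
                 class = "cryoclean_argument_error")
  }
  as.integer(min_reads)
}

#' Identify contaminant OTUs from background controls
#'
#' An OTU is flagged as a contaminant iff it is present (>= `min_reads`
#' reads) in at least one control sample. The processing-control set (PC)
#' and DNA-extraction-control set (DC) are built from the respective sample
#' roles (multiple controls of the same role are unioned -- the conservative
#' reading of "detected in the controls"), each contaminant gets a
#' provenance label (`pc_only`, `dc_only`, `shared`), and the PC-DC set --
#' the contaminants exclusive to the processing control after subtracting
#' everything shared with the extraction control -- is precomputed.
#'
#' @param x An [otu_tbl()].
#' @param sheet A [sample_sheet()] covering every sample in `x` and
#'   containing at least one control sample (otherwise the function
#'   refuses).
#' @param min_reads Detection threshold, see [call_presence()].
#' @return A `contaminant_catalog`: use `tidy()` for the per-OTU table
#'   (`otu_id`, `provenance`, `in_pc`, `in_dc`), `glance()` for the
#'   partition sizes, [pc_minus_dc()] for the exclusive set, and `$pc_set`,
#'   `$dc_set`, `$contaminant_otu_ids` directly.
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' glance(cat)
#' @export
identify_contaminants <- function(x, sheet, min_reads = 1L) {
  x <- as_otu_tbl(x)
  sheet <- check_sheet_matches(x, sheet)
  min_reads <- check_min_reads(min_reads)
  ctrl_ids <- samples_with_role(sheet, control_roles)
  if (length(ctrl_ids) == 0L) {
    rlang::abort(
      paste(
        "no control samples in the sample sheet: contaminant identification",
        "needs at least one processing_control or extraction_control sample."
      ),
      class = "cryoclean_no_controls_error"
    )
  }
  warnings <- character()
  zero_ctrl <- ctrl_ids[sample_totals(x)[ctrl_ids] == 0]
  if (length(zero_ctrl)) {
    warnings <- paste0("control sample with zero total reads: ",
                       paste(zero_ctrl, collapse = ", "))
    rlang::warn(warnings)
  }
  pres <- call_presence(x, min_reads)
  present_in <- function(ids) {
    if (length(ids) == 0L) return(character())
    m <- as.matrix(pres[, ids, drop = FALSE])
    pres$otu_id[rowSums(m) > 0]
  }
  pc_set <- present_in(samples_with_role(sheet, "processing_control"))
  dc_set <- present_in(samples_with_role(sheet, "extraction_control"))
  contaminants <- otu_ids(x)[otu_ids(x) %in% union(pc_set, dc_set)]
  provenance <- dplyr::case_when(
    contaminants %in% pc_set & contaminants %in% dc_set ~ "shared",
    contaminants %in% pc_set ~ "pc_only",
    TRUE ~ "dc_only"
  )
  structure(
    list(
      contaminant_otu_ids = contaminants,
      provenance = stats::setNames(provenance, contaminants),
      pc_set = contaminants[contaminants %in% pc_set],
      dc_set = contaminants[contaminants %in% dc_set],
      pc_minus_dc_set = contaminants[contaminants %in% setdiff(pc_set, dc_set)],
      min_reads = min_reads,
      warnings = warnings
    ),
    class = "contaminant_catalog"
  )
}

#' @export
print.contaminant_catalog <- function(x, ...) {
  g <- glance(x)
  cat("<contaminant_catalog> ", g$n_contaminants, " contaminant OTU(s) at >= ",
      x$min_reads, " read(s)\n", sep = "")
  cat("  PC: ", g$n_pc, "  DC: ", g$n_dc, "  shared: ", g$n_shared,
      "  PC-DC: ", g$n_pc_minus_dc, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.contaminant_catalog <- function(x, ...) {
  tibble::tibble(
    otu_id = x$contaminant_otu_ids,
    provenance = unname(x$provenance),
    in_pc = x$contaminant_otu_ids %in% x$pc_set,
    in_dc = x$contaminant_otu_ids %in% x$dc_set
  )
}

#' @export
glance.contaminant_catalog <- function(x, ...) {
  tibble::tibble(
    n_contaminants = length(x$contaminant_otu_ids),
    n_pc = length(x$pc_set),
    n_dc = length(x$dc_set),
    n_shared = sum(x$provenance == "shared"),
    n_pc_only = sum(x$provenance == "pc_only"),
    n_dc_only = sum(x$provenance == "dc_only"),
    n_pc_minus_dc = length(x$pc_minus_dc_set),
    min_reads = x$min_reads
  )
}

#' Contaminants exclusive to the processing control (PC-DC)
#'
#' The in-silico subtraction that isolates handling/equipment contamination:
#' every contaminant also detected in the DNA-extraction control is
#' subtracted from the processing-control set, leaving only the OTUs
#' exclusive to processing.
#'
#' @param catalog A [identify_contaminants()] catalog.
#' @return Character vector of OTU ids (set difference PC \ DC).
#' @export
pc_minus_dc <- function(catalog) {
  stopifnot(inherits(catalog, "contaminant_catalog"))
  catalog$pc_minus_dc_set
}

#' Overlap of contaminants with the environmental samples
#'
#' Classifies every catalogued contaminant by where it also occurs in the
#' environment: only in ice, only in water, in both, or in neither (a
#' control-exclusive contaminant). With `pooled = TRUE` (the display
#' convention for replicate sets) replicate samples within each
#' environmental replicate group are unioned before intersecting.
#'
#' @param catalog A [identify_contaminants()] catalog.
#' @param x The [otu_tbl()] the catalog was built from.
#' @param sheet The matching [sample_sheet()].
#' @param min_reads Detection threshold; defaults to the catalog's.
#' @param pooled Union replicates per role before intersecting.
#' @return An `overlap_report`; `tidy()` gives the per-OTU classification,
#'   `glance()` the counts (`n_in_env`, `ice_only`, `water_only`, `both`,
#'   `neither`).
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' glance(environmental_overlap(cat, seaice_counts(), seaice_samples()))
#' @export
environmental_overlap <- function(catalog, x, sheet,
                                  min_reads = catalog$min_reads,
                                  pooled = TRUE) {
  stopifnot(inherits(catalog, "contaminant_catalog"))
  x <- as_otu_tbl(x)
  sheet <- check_sheet_matches(x, sheet)
  pres <- call_presence(x, min_reads)
  in_any <- function(ids) {
    if (length(ids) == 0L) return(rep(FALSE, nrow(pres)))
    rowSums(as.matrix(pres[, ids, drop = FALSE])) > 0
  }
  ice_ids <- samples_with_role(sheet, "environmental_ice")
  water_ids <- samples_with_role(sheet, "environmental_water")
  # pooling unions replicates; per-OTU presence in >=1 member sample either way
  in_ice <- in_any(ice_ids)
  in_water <- in_any(water_ids)
  keep <- pres$otu_id %in% catalog$contaminant_otu_ids
  detail <- tibble::tibble(
    otu_id = pres$otu_id[keep],
    in_ice = in_ice[keep],
    in_water = in_water[keep],
    category = dplyr::case_when(
      in_ice[keep] & in_water[keep] ~ "both",
      in_ice[keep] ~ "ice_only",
      in_water[keep] ~ "water_only",
      TRUE ~ "neither"
    )
  )
  structure(list(detail = detail, pooled = pooled, min_reads = min_reads),
            class = "overlap_report")
}

#' @export
tidy.overlap_report <- function(x, ...) x$detail

#' @export
glance.overlap_report <- function(x, ...) {
  d <- x$detail
  tibble::tibble(
    n_contaminants = nrow(d),
    n_in_env = sum(d$category != "neither"),
    ice_only = sum(d$category == "ice_only"),
    water_only = sum(d$category == "water_only"),
    both = sum(d$category == "both"),
    neither = sum(d$category == "neither")
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  g <- glance(x)
  cat("<overlap_report> ", g$n_in_env, " of ", g$n_contaminants,
      " contaminants present in environmental samples\n", sep = "")
  cat("  ice-only: ", g$ice_only, "  water-only: ", g$water_only,
      "  both: ", g$both, "  neither: ", g$neither, "\n", sep = "")
  invisible(x)
}
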