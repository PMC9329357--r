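#' Per-sample relative abundances
#'
#' Converts read counts to percent of each sample's total on the
#' non-rarefied table (rarefying would lose or misrepresent exactly the low
#' abundance OTUs contamination monitoring cares about). Per-sample
#' denominators are recorded; a zero-total sample yields an all-zero column
#' and is flagged as undefined rather than failing.
#'
#' @param x An [otu_tbl()] (or coercible data frame).
#' @return A `relabund_tbl`: tibble of percents on the same axes as `x`,
#'   with attributes `denominators` (named reads-per-sample vector) and
#'   `undefined_samples` (ids of zero-total samples).
#' @examples
#' relative_abundance(seaice_counts())
#' @export
relative_abundance <- function(x) {
  x <- as_otu_tbl(x)
  denom <- sample_totals(x)
  out <- tibble::as_tibble(x)
  for (s in sample_ids(x)) {
    out[[s]] <- if (denom[[s]] == 0) 0 else 100 * x[[s]] / denom[[s]]
  }
  new_relabund(out, denom, names(denom)[denom == 0])
}

new_relabund <- function(tbl, denominators, undefined) {
  attr(tbl, "denominators") <- denominators
  attr(tbl, "undefined_samples") <- undefined
  class(tbl) <- unique(c("relabund_tbl", class(tbl)))
  tbl
}

#' @rdname relative_abundance
#' @param percents A data frame already holding percent values (`otu_id`
#'   first column) -- e.g. a published relative-abundance table whose read
#'   denominators are not available.
#' @param denominators Optional named vector of per-sample read totals.
#' @export
as_relabund <- function(percents, denominators = NULL) {
  percents <- tibble::as_tibble(percents)
  stopifnot(names(percents)[1] == "otu_id")
  samples <- names(percents)[-1]
  if (is.null(denominators)) {
    denominators <- stats::setNames(rep(NA_real_, length(samples)), samples)
  }
  new_relabund(percents, denominators, character())
}

relabund_samples <- function(ra) names(ra)[-1]

#' Total contaminant load of the environmental samples
#'
#' Sums the relative abundances of the catalogued contaminants per
#' environmental sample, and reports their mean and sample standard
#' deviation (n - 1 denominator) across those samples, together with the
#' same statistics per contaminant OTU. This is the "total contamination
#' abundance" summary of a monitoring report: low-biomass surveys with
#' clean handling typically keep it well under 1%.
#'
#' @param relabund A [relative_abundance()] result (or [as_relabund()] on a
#'   published percentage table).
#' @param catalog The [identify_contaminants()] catalog.
#' @param sheet The matching [sample_sheet()]; only environmental samples
#'   enter the statistics.
#' @return A `contaminant_load`: `tidy()` gives the per-OTU mean +/- sd,
#'   `glance()` the per-dataset mean +/- sd of the per-sample totals, and
#'   `$per_sample` the totals themselves.
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' load <- contaminant_load(as_relabund(seaice_contaminant_abundance()),
#'                          cat, seaice_samples())
#' glance(load)
#' @export
contaminant_load <- function(relabund, catalog, sheet) {
  stopifnot(inherits(catalog, "contaminant_catalog"))
  sheet <- sample_sheet(sheet)
  env_ids <- intersect(relabund_samples(relabund),
                       samples_with_role(sheet, env_roles))
  if (length(env_ids) == 0L) {
    abort_format("no environmental samples among the relative-abundance columns.")
  }
  sub <- relabund[relabund$otu_id %in% catalog$contaminant_otu_ids, , drop = FALSE]
  m <- as.matrix(sub[, env_ids, drop = FALSE])
  rownames(m) <- sub$otu_id
  per_sample <- tibble::tibble(
    sample_id = env_ids,
    total_pct = unname(colSums(m))
  )
  per_otu <- tibble::tibble(
    otu_id = rownames(m),
    mean_pct = unname(rowMeans(m)),
    sd_pct = unname(apply(m, 1L, stats::sd))
  )
  structure(
    list(
      per_sample = per_sample,
      per_otu = per_otu,
      mean_total_pct = mean(per_sample$total_pct),
      sd_total_pct = stats::sd(per_sample$total_pct)
    ),
    class = "contaminant_load"
  )
}

#' @export
tidy.contaminant_load <- function(x, ...) x$per_otu

#' @export
glance.contaminant_load <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$per_sample),
    mean_total_pct = x$mean_total_pct,
    sd_total_pct = x$sd_total_pct
  )
}

#' @export
print.contaminant_load <- function(x, ...) {
  cat("<contaminant_load> mean total contaminant abundance ",
      round(x$mean_total_pct, 2), "% +/- ", signif(x$sd_total_pct, 1),
      " across ", nrow(x$per_sample), " environmental sample(s)\n", sep = "")
  invisible(x)
}

#' Pooled presence sets per replicate group and control role
#'
#' Builds, for each environmental replicate group and each control role,
#' the set of OTUs present (>= `min_reads` reads) in at least one member
#' sample -- the pooling convention used when drawing replicate sets in a
#' Venn diagram.
#'
#' @inheritParams call_presence
#' @param sheet A [sample_sheet()] covering the samples of `x`.
#' @return A named list of character vectors (one set per group).
#' @examples
#' sets <- pool_presence(seaice_counts(), seaice_samples())
#' names(sets)
#' @export
pool_presence <- function(x, sheet, min_reads = 1L) {
  x <- as_otu_tbl(x)
  sheet <- check_sheet_matches(x, sheet)
  pres <- call_presence(x, min_reads)
  env <- sheet[sheet$role %in% env_roles, , drop = FALSE]
  groups <- c(
    split(env$sample_id, env$replicate_group),
    lapply(
      stats::setNames(control_roles, control_roles),
      function(r) samples_with_role(sheet, r)
    )
  )
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  lapply(groups, function(ids) {
    pres$otu_id[rowSums(as.matrix(pres[, ids, drop = FALSE])) > 0]
  })
}

#' Venn partition of 2 or 3 named sets
#'
#' Computes the cardinality of every intersection region (2^k - 1 regions
#' for k sets) by assigning each element of the union to exactly one
#' region, so region sizes always sum to the union cardinality.
#'
#' @param sets A named list of 2 or 3 character vectors (or a data frame
#'   with columns `group` and `otu_id`).
#' @return A `venn_partition`: `tidy()` gives one row per region with its
#'   size and membership pattern; `autoplot()` draws the diagram.
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' tidy(venn_partition(list(PC = cat$pc_set, DC = cat$dc_set)))
#' @export
venn_partition <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("group", "otu_id") %in% names(sets)))
    sets <- split(sets$otu_id, sets$group)
  }
  k <- length(sets)
  if (k < 2L || k > 3L) {
    rlang::abort("`venn_partition()` supports 2 or 3 sets.",
                 class = "cryoclean_arity_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    rlang::abort("sets must be named.", class = "cryoclean_argument_error")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- names(sets)
  # binary region code per element of the union, then count per pattern
  codes <- as.vector(membership %*% 2^(seq_len(k) - 1L))
  regions <- purrr::pmap(patterns, function(...) {
    want <- c(...)
    code <- sum(2^(which(want) - 1L))
    hit <- codes == code
    list(
      region = paste(names(sets)[want], collapse = "&"),
      size = sum(hit),
      members = universe[hit]
    )
  })
  tbl <- tibble::tibble(
    region = vapply(regions, `[[`, character(1), "region"),
    size = vapply(regions, function(r) as.integer(r$size), integer(1))
  )
  for (nm in names(sets)) tbl[[paste0("in_", nm)]] <- patterns[[nm]]
  structure(
    list(regions = tbl,
         members = stats::setNames(lapply(regions, `[[`, "members"), tbl$region),
         set_names = names(sets),
         union_size = length(universe)),
    class = "venn_partition"
  )
}

#' @export
tidy.venn_partition <- function(x, ...) x$regions

#' @export
glance.venn_partition <- function(x, ...) {
  tibble::tibble(n_sets = length(x$set_names), union_size = x$union_size)
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> ", length(x$set_names), " sets, union of ",
      x$union_size, " elements\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Taxonomic composition with an "Others" category
#'
#' Aggregates a relative-abundance table to one taxonomic rank per sample.
#' OTUs that are unclassified at the rank -- missing label, or classifier
#' confidence below the 70% convention -- are grouped under
#' `"unclassified"`. Taxa that stay strictly below `others_threshold`
#' percent in **every** sample are merged into `"Others"` (a taxon at or
#' above the threshold in any one sample keeps its own row -- the readable
#' stacked-bar convention). Columns of nonzero samples still sum to 100.
#'
#' @param relabund A [relative_abundance()] result.
#' @param taxonomy A [taxonomy_tbl()] covering the OTUs of `relabund`.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @param others_threshold Percent below which a taxon is merged (strict).
#' @param min_confidence Classifier-confidence convention for "classified
#'   at the rank".
#' @return A tibble with `taxon` plus one percent column per sample;
#'   `"Others"` and `"unclassified"` rows last when present.
#' @examples
#' ra <- relative_abundance(seaice_counts())
#' aggregate_taxa(ra, seaice_taxonomy(), rank = "genus")
#' @export
aggregate_taxa <- function(relabund, taxonomy, rank = "genus",
                           others_threshold = 0.5, min_confidence = 0.70) {
  rank <- match.arg(rank, setdiff(taxonomy_ranks, "domain"))
  taxonomy <- require_taxonomy(relabund, taxonomy)
  samples <- relabund_samples(relabund)
  tax <- taxonomy[match(relabund$otu_id, taxonomy$otu_id), ]
  label <- tax[[rank]]
  unclassified <- is.na(label) |
    (!is.na(tax$confidence) & tax$confidence < min_confidence)
  label[unclassified] <- "unclassified"
  agg <- tibble::as_tibble(relabund) |>
    dplyr::mutate(taxon = label) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum),
                     .groups = "drop")
  m <- as.matrix(agg[, samples, drop = FALSE])
  keep <- apply(m, 1L, max) >= others_threshold | agg$taxon == "unclassified"
  shown <- agg[keep & agg$taxon != "unclassified", , drop = FALSE] |>
    dplyr::arrange(.data$taxon)
  others <- agg[!keep & agg$taxon != "unclassified", , drop = FALSE]
  out <- shown
  if (nrow(others)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::summarise(
        others, taxon = "Others",
        dplyr::across(dplyr::all_of(samples), sum)
      )
    )
  }
  uncl <- agg[agg$taxon == "unclassified", , drop = FALSE]
  if (nrow(uncl)) out <- dplyr::bind_rows(out, uncl)
  out
}
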