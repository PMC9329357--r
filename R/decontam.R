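#' In-silico decontamination of environmental samples
#'
#' Four strategies for removing control-detected contaminants from the
#' environmental fraction of an OTU table. Removal means dropping the OTU
#' row from the cleaned table entirely (the removal ledger keeps the audit
#' trail); control columns are excluded from the cleaned output. Every
#' strategy only ever removes OTUs that are in the catalog, so the
#' conservative strategy is the superset of all others.
#'
#' * `decontaminate_conservative()`: remove **all** catalogued contaminants
#'   -- the approach of choice when false-positive environmental signal is
#'   more costly than lost diversity (e.g. life detection / planetary
#'   protection).
#' * `decontaminate_by_control_abundance()`: remove contaminants whose
#'   relative abundance in the controls (percent of that control sample's
#'   reads, maximum over control samples) is strictly above `threshold`.
#' * `decontaminate_high_abundance()`: remove the `top_k` contaminants
#'   ranked by mean relative abundance across control samples (ties broken
#'   by lexicographic `otu_id`; "high abundance" is under-specified in
#'   common usage, so the cut is exposed as an explicit rank count).
#' * `decontaminate_by_ratio()`: remove contaminants whose mean relative
#'   abundance across control samples strictly exceeds their mean relative
#'   abundance across environmental samples.
#'
#' Relative abundances are computed per sample on the non-rarefied table,
#' then averaged unweighted across the samples of the relevant role. A
#' control sample with zero reads contributes no abundances (with a
#' warning).
#'
#' @param x A curated [otu_tbl()] containing environmental and control
#'   samples.
#' @param catalog The [identify_contaminants()] catalog for `x`.
#' @param sheet The matching [sample_sheet()].
#' @return A `decontam_result`: `$cleaned` is the cleaned `otu_tbl`
#'   (environmental samples only), `tidy()` the per-OTU ledger (removed
#'   flag plus reads removed per environmental sample, long form), and
#'   `glance()` the totals (reads before/after/removed, OTUs removed).
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' res <- decontaminate_conservative(seaice_counts(), cat, seaice_samples())
#' glance(res)
#' @export
decontaminate_conservative <- function(x, catalog, sheet) {
  prep <- decontam_prep(x, catalog, sheet)
  build_decontam_result(prep, prep$catalog_ids, "conservative", list())
}

#' @rdname decontaminate_conservative
#' @param threshold Percent of control-sample reads; contaminants strictly
#'   above it (max over control samples) are removed. `threshold = 0`
#'   reproduces the conservative strategy; `threshold = 100` removes
#'   nothing.
#' @export
decontaminate_by_control_abundance <- function(x, catalog, sheet, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  prep <- decontam_prep(x, catalog, sheet)
  pct <- control_percent_matrix(prep)
  max_pct <- apply(pct, 1L, function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  remove <- prep$catalog_ids[max_pct[prep$catalog_ids] > threshold]
  build_decontam_result(prep, remove, "control_abundance_threshold",
                        list(threshold = threshold))
}

#' @rdname decontaminate_conservative
#' @param top_k Number of top-ranked contaminants to remove. If `top_k`
#'   exceeds the catalog size, all catalogued contaminants are removed with
#'   a warning.
#' @export
decontaminate_high_abundance <- function(x, catalog, sheet, top_k) {
  stopifnot(is.numeric(top_k), length(top_k) == 1L, top_k >= 1,
            top_k == trunc(top_k))
  prep <- decontam_prep(x, catalog, sheet)
  if (top_k > length(prep$catalog_ids)) {
    rlang::warn("`top_k` exceeds the catalog size; removing all catalogued contaminants.")
    top_k <- length(prep$catalog_ids)
  }
  pct <- control_percent_matrix(prep)
  mean_pct <- rowMeans(pct, na.rm = TRUE)[prep$catalog_ids]
  mean_pct[is.nan(mean_pct)] <- 0
  ord <- order(-mean_pct, prep$catalog_ids)
  remove <- prep$catalog_ids[ord][seq_len(top_k)]
  build_decontam_result(prep, remove, "high_abundance", list(top_k = top_k))
}

#' @rdname decontaminate_conservative
#' @export
decontaminate_by_ratio <- function(x, catalog, sheet) {
  prep <- decontam_prep(x, catalog, sheet)
  if (length(prep$env_ids) == 0L) {
    abort_format("no environmental samples in the sample sheet.")
  }
  ctrl_pct <- control_percent_matrix(prep)
  env_pct <- percent_matrix(prep$x, prep$env_ids)
  ctrl_mean <- rowMeans(ctrl_pct, na.rm = TRUE)
  ctrl_mean[is.nan(ctrl_mean)] <- 0
  env_mean <- rowMeans(env_pct, na.rm = TRUE)
  env_mean[is.nan(env_mean)] <- 0
  remove <- prep$catalog_ids[ctrl_mean[prep$catalog_ids] > env_mean[prep$catalog_ids]]
  build_decontam_result(prep, remove, "control_vs_sample_ratio", list())
}

#' @rdname decontaminate_conservative
#' @param strategy Strategy name; dispatches to one of the four functions.
#' @param ... Strategy parameters (`threshold`, `top_k`).
#' @export
decontaminate <- function(x, catalog, sheet,
                          strategy = c("conservative", "control_abundance",
                                       "high_abundance", "ratio"),
                          ...) {
  strategy <- match.arg(strategy)
  switch(strategy,
    conservative = decontaminate_conservative(x, catalog, sheet),
    control_abundance = decontaminate_by_control_abundance(x, catalog, sheet, ...),
    high_abundance = decontaminate_high_abundance(x, catalog, sheet, ...),
    ratio = decontaminate_by_ratio(x, catalog, sheet)
  )
}

decontam_prep <- function(x, catalog, sheet) {
  stopifnot(inherits(catalog, "contaminant_catalog"))
  x <- as_otu_tbl(x)
  sheet <- check_sheet_matches(x, sheet)
  unknown <- setdiff(catalog$contaminant_otu_ids, otu_ids(x))
  if (length(unknown)) {
    abort_format(paste0(
      "catalog references OTU(s) unknown to the table: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  list(
    x = x, sheet = sheet, catalog = catalog,
    catalog_ids = catalog$contaminant_otu_ids,
    env_ids = samples_with_role(sheet, env_roles),
    ctrl_ids = samples_with_role(sheet, control_roles)
  )
}

# percent-of-sample matrix restricted to `ids`; zero-read samples give NA
percent_matrix <- function(x, ids) {
  m <- counts_matrix(x)[, ids, drop = FALSE]
  totals <- colSums(m)
  out <- sweep(m, 2L, totals, "/") * 100
  out[, totals == 0] <- NA_real_
  out
}

control_percent_matrix <- function(prep) {
  zero <- prep$ctrl_ids[sample_totals(prep$x)[prep$ctrl_ids] == 0]
  if (length(zero)) {
    rlang::warn(paste0(
      "control sample(s) with zero reads contribute no abundances: ",
      paste(zero, collapse = ", ")
    ))
  }
  percent_matrix(prep$x, prep$ctrl_ids)
}

build_decontam_result <- function(prep, remove_ids, strategy, parameters) {
  env <- keep_samples(prep$x, prep$env_ids)
  attr(env, "curation_ledger") <- NULL # cleaned output is a fresh table
  cleaned <- drop_otus(env, remove_ids)
  ledger <- tidyr::expand_grid(otu_id = otu_ids(env), sample_id = prep$env_ids) |>
    dplyr::mutate(
      removed = .data$otu_id %in% remove_ids,
      reads_removed = ifelse(
        .data$removed,
        counts_matrix(env)[cbind(.data$otu_id, .data$sample_id)],
        0L
      )
    )
  reads_before <- sum(sample_totals(env))
  reads_removed <- sum(ledger$reads_removed)
  structure(
    list(
      cleaned = cleaned,
      removed_otu_ids = remove_ids,
      ledger = ledger,
      strategy = strategy,
      parameters = parameters,
      reads_before = reads_before,
      reads_after = reads_before - reads_removed,
      reads_removed = reads_removed,
      otus_before = nrow(env),
      otus_after = nrow(cleaned)
    ),
    class = "decontam_result"
  )
}

#' @export
tidy.decontam_result <- function(x, ...) x$ledger

#' @export
glance.decontam_result <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    otus_before = x$otus_before,
    otus_after = x$otus_after,
    otus_removed = length(x$removed_otu_ids),
    reads_before = x$reads_before,
    reads_after = x$reads_after,
    reads_removed = x$reads_removed
  )
}

#' @export
print.decontam_result <- function(x, ...) {
  cat("<decontam_result> strategy: ", x$strategy, "\n", sep = "")
  cat("  removed ", length(x$removed_otu_ids), " OTU(s), ",
      x$reads_removed, " read(s); cleaned table: ", x$otus_after,
      " OTU(s) x ", length(sample_ids(x$cleaned)), " sample(s)\n", sep = "")
  invisible(x)
}
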