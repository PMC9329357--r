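#' Dataset curation filters
#'
#' The standard OTU-table-level curation that precedes any contamination
#' analysis, applied in a fixed order: (1) drop OTUs that could not be
#' classified at the domain level (identity strictly below `min_identity`;
#' ties are retained), (2) drop non-prokaryotic OTUs (eukaryotes, then
#' chloroplasts, then mitochondria -- the first matching reason wins, no OTU
#' is removed twice), (3) drop singletons, i.e. OTUs with a single read in
#' the whole dataset. Sequence-level steps (length filtering, chimera
#' removal) happen upstream of the OTU table and are out of scope here.
#'
#' Each filter returns the filtered [otu_tbl()] with a cumulative removal
#' ledger attached, so the filters chain naturally with the pipe. Retrieve
#' the ledger with [curation_ledger()]; `tidy()` on the ledger gives
#' per-reason counts and `glance()` the before/after totals.
#'
#' @param x An [otu_tbl()] (possibly already carrying a ledger).
#' @param taxonomy A [taxonomy_tbl()] covering every OTU in `x` (a missing
#'   record is an error naming the OTU; taxonomy supersets are fine).
#' @param min_identity Domain-level identity threshold; OTUs with
#'   `confidence` strictly below it are removed. OTUs with `NA` confidence
#'   cannot be assessed and are retained.
#' @return The filtered `otu_tbl` with a `curation_ledger` attribute.
#' @examples
#' tab <- seaice_counts() |> filter_singletons()
#' glance(curation_ledger(tab))
#' @export
filter_domain_unclassified <- function(x, taxonomy, min_identity = 0.70) {
  x <- as_otu_tbl(x)
  taxonomy <- require_taxonomy(x, taxonomy)
  conf <- taxonomy$confidence[match(otu_ids(x), taxonomy$otu_id)]
  remove <- otu_ids(x)[!is.na(conf) & conf < min_identity]
  apply_curation(x, remove, "domain_unclassified")
}

#' @rdname filter_domain_unclassified
#' @export
filter_nonprokaryotic <- function(x, taxonomy) {
  x <- as_otu_tbl(x)
  taxonomy <- require_taxonomy(x, taxonomy)
  tax <- taxonomy[match(otu_ids(x), taxonomy$otu_id), ]
  is_euk <- !is.na(tax$domain) & tax$domain == "Eukaryota"
  is_chl <- !is_euk & tax$organelle_flag == "chloroplast"
  is_mit <- !is_euk & !is_chl & tax$organelle_flag == "mitochondria"
  x <- apply_curation(x, tax$otu_id[is_euk], "eukaryote")
  x <- apply_curation(x, intersect(otu_ids(x), tax$otu_id[is_chl]),
                      "chloroplast")
  apply_curation(x, intersect(otu_ids(x), tax$otu_id[is_mit]), "mitochondria")
}

#' @rdname filter_domain_unclassified
#' @export
filter_singletons <- function(x) {
  x <- as_otu_tbl(x)
  totals <- rowSums(counts_matrix(x))
  apply_curation(x, otu_ids(x)[totals == 1], "singleton")
}

#' @rdname filter_domain_unclassified
#' @param min_domain_identity Passed to [filter_domain_unclassified()].
#' @param remove_singletons Whether to apply [filter_singletons()].
#' @export
curate <- function(x, taxonomy, min_domain_identity = 0.70,
                   remove_singletons = TRUE) {
  x <- filter_domain_unclassified(x, taxonomy, min_domain_identity)
  x <- filter_nonprokaryotic(x, taxonomy)
  if (remove_singletons) x <- filter_singletons(x)
  x
}

#' @rdname filter_domain_unclassified
#' @export
curation_ledger <- function(x) {
  led <- attr(x, "curation_ledger")
  if (is.null(led)) {
    led <- empty_ledger(as_otu_tbl(x))
  }
  led
}

curation_reasons <- c("domain_unclassified", "eukaryote", "chloroplast",
                      "mitochondria", "singleton")

empty_ledger <- function(x) {
  led <- tibble::tibble(reason = character(), otu_id = character(),
                        reads_removed = integer())
  attr(led, "otus_before") <- nrow(x)
  attr(led, "reads_before") <- total_reads(x)
  attr(led, "otus_after") <- nrow(x)
  attr(led, "reads_after") <- total_reads(x)
  class(led) <- unique(c("curation_ledger", class(led)))
  led
}

apply_curation <- function(x, remove_ids, reason) {
  led <- attr(x, "curation_ledger")
  if (is.null(led)) led <- empty_ledger(x)
  # idempotence: an OTU already logged can no longer be in `x`
  remove_ids <- intersect(remove_ids, otu_ids(x))
  if (length(remove_ids)) {
    removed <- x[x$otu_id %in% remove_ids, , drop = FALSE]
    entry <- tibble::tibble(
      reason = reason,
      otu_id = removed$otu_id,
      reads_removed = as.integer(rowSums(counts_matrix(removed)))
    )
    new_led <- dplyr::bind_rows(led, entry)
    attributes(new_led)[c("otus_before", "reads_before")] <-
      attributes(led)[c("otus_before", "reads_before")]
    class(new_led) <- unique(c("curation_ledger", class(new_led)))
    led <- new_led
    x <- drop_otus(x, remove_ids)
  }
  attr(led, "otus_after") <- nrow(x)
  attr(led, "reads_after") <- total_reads(x)
  attr(x, "curation_ledger") <- led
  x
}

#' @export
tidy.curation_ledger <- function(x, ...) {
  tibble::as_tibble(x)[, c("reason", "otu_id", "reads_removed")] |>
    dplyr::group_by(.data$reason) |>
    dplyr::summarise(otus_removed = dplyr::n(),
                     reads_removed = sum(.data$reads_removed),
                     .groups = "drop")
}

#' @export
glance.curation_ledger <- function(x, ...) {
  tibble::tibble(
    otus_before = attr(x, "otus_before"),
    otus_after = attr(x, "otus_after"),
    otus_removed = nrow(x),
    reads_before = attr(x, "reads_before"),
    reads_after = attr(x, "reads_after"),
    reads_removed = sum(x$reads_removed)
  )
}

require_taxonomy <- function(x, taxonomy) {
  taxonomy <- taxonomy_tbl(taxonomy)
  missing <- setdiff(x$otu_id, taxonomy$otu_id)
  if (length(missing)) {
    abort_format(paste0(
      "no taxonomy record for OTU(s): ", paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  taxonomy
}
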