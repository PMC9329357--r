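#' OTU count tables
#'
#' An `otu_tbl` is an ordinary tibble of non-negative integer read counts
#' with one row per OTU and one column per sample, plus a leading `otu_id`
#' character column. `otu_tbl()` validates a data frame and stamps the
#' class; every function in the package that consumes counts accepts either
#' an `otu_tbl` or a plain data frame of the same shape (it is validated on
#' the way in).
#'
#' Invariants enforced here:
#' * all counts are integral and >= 0 (missing cells are an error, never a
#'   silent zero);
#' * `otu_id` values and sample column names are unique;
#' * per-sample totals are recomputable as plain column sums.
#'
#' @param x A data frame whose first column is `otu_id` and whose remaining
#'   columns are per-sample read counts.
#' @return A validated `otu_tbl` (a tibble).
#' @examples
#' otu_tbl(data.frame(otu_id = c("a", "b"), s1 = c(3L, 0L), s2 = c(1L, 2L)))
#' @export
otu_tbl <- function(x) {
  if (!is.data.frame(x)) {
    abort_format("`x` must be a data frame of OTU counts.")
  }
  x <- tibble::as_tibble(x, .name_repair = "minimal")
  if (ncol(x) < 1L || names(x)[1] != "otu_id") {
    abort_format("the first column must be `otu_id`.")
  }
  x$otu_id <- as.character(x$otu_id)
  if (anyDuplicated(x$otu_id)) {
    dup <- unique(x$otu_id[duplicated(x$otu_id)])
    abort_format(paste0("duplicate otu_id: ", paste(dup, collapse = ", ")))
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    abort_format(paste0("duplicate sample id: ", paste(dup, collapse = ", ")))
  }
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort_format(paste0("sample `", s, "` holds non-numeric counts."))
    }
    bad <- which(is.na(v) | v < 0 | v != trunc(v))
    if (length(bad)) {
      abort_format(paste0(
        "invalid count at otu `", x$otu_id[bad[1]], "`, sample `", s,
        "`: counts must be non-negative integers."
      ))
    }
    x[[s]] <- as.integer(v)
  }
  class(x) <- unique(c("otu_tbl", class(x)))
  x
}

#' @rdname otu_tbl
#' @export
is_otu_tbl <- function(x) inherits(x, "otu_tbl")

as_otu_tbl <- function(x) if (is_otu_tbl(x)) x else otu_tbl(x)

#' Axis and total helpers for OTU tables
#'
#' @param x An `otu_tbl` (or data frame coercible to one).
#' @return `otu_ids()` and `sample_ids()` return character vectors;
#'   `sample_totals()` a named integer vector of per-sample read totals;
#'   `total_reads()` a single number.
#' @export
otu_ids <- function(x) as_otu_tbl(x)$otu_id

#' @rdname otu_ids
#' @export
sample_ids <- function(x) names(as_otu_tbl(x))[-1]

#' @rdname otu_ids
#' @export
sample_totals <- function(x) {
  x <- as_otu_tbl(x)
  ids <- sample_ids(x)
  vapply(ids, function(s) sum(x[[s]]), numeric(1))
}

#' @rdname otu_ids
#' @export
total_reads <- function(x) sum(sample_totals(x))

counts_matrix <- function(x) {
  x <- as_otu_tbl(x)
  m <- as.matrix(x[, sample_ids(x), drop = FALSE])
  rownames(m) <- x$otu_id
  storage.mode(m) <- "integer"
  m
}

keep_samples <- function(x, ids) {
  x <- as_otu_tbl(x)
  out <- x[, c("otu_id", ids), drop = FALSE]
  class(out) <- unique(c("otu_tbl", class(out)))
  out
}

drop_otus <- function(x, ids) {
  x <- as_otu_tbl(x)
  out <- x[!x$otu_id %in% ids, , drop = FALSE]
  class(out) <- unique(c("otu_tbl", class(out)))
  out
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "cryoclean_format_error")
}
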