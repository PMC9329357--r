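circle_points <- function(cx, cy, r, n = 200) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x = cx + r * cos(t), y = cy + r * sin(t))
}

#' Venn diagram of a set partition
#'
#' Draws the 2- or 3-circle diagram for a [venn_partition()], with region
#' cardinalities as labels. Layout is schematic (fixed congruent circles),
#' not area-proportional.
#'
#' @param object A `venn_partition`.
#' @param ... Ignored.
#' @return A ggplot.
#' @examples
#' cat <- identify_contaminants(seaice_counts(), seaice_samples())
#' autoplot(venn_partition(list(PC = cat$pc_set, DC = cat$dc_set)))
#' @export
autoplot.venn_partition <- function(object, ...) {
  k <- length(object$set_names)
  centers <- if (k == 2) {
    tibble::tibble(set = object$set_names, cx = c(-0.5, 0.5), cy = c(0, 0))
  } else {
    tibble::tibble(set = object$set_names,
                   cx = c(-0.5, 0.5, 0), cy = c(0.3, 0.3, -0.6))
  }
  circles <- purrr::pmap_dfr(centers, function(set, cx, cy) {
    dplyr::mutate(circle_points(cx, cy, 1), set = set)
  })
  labels <- region_label_positions(object, centers)
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = circles,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$set,
                   fill = .data$set),
      alpha = 0.3, colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$size),
      size = 5
    ) +
    ggplot2::geom_text(
      data = centers,
      ggplot2::aes(x = .data$cx, y = .data$cy + 1.15, label = .data$set),
      fontface = "bold"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

region_label_positions <- function(object, centers) {
  reg <- object$regions
  memb <- as.matrix(reg[, paste0("in_", object$set_names), drop = FALSE])
  pos <- t(vapply(seq_len(nrow(reg)), function(i) {
    inside <- which(memb[i, ])
    outside <- which(!memb[i, ])
    x <- mean(centers$cx[inside])
    y <- mean(centers$cy[inside])
    if (length(outside) && length(inside) == 1L) {
      # push exclusive regions away from the other circles
      dx <- x - mean(centers$cx[outside])
      dy <- y - mean(centers$cy[outside])
      nrm <- sqrt(dx^2 + dy^2)
      if (nrm > 0) {
        x <- x + 0.45 * dx / nrm
        y <- y + 0.45 * dy / nrm
      }
    }
    c(x, y)
  }, numeric(2)))
  tibble::tibble(x = pos[, 1], y = pos[, 2], size = reg$size)
}

#' Stacked-bar taxonomic composition
#'
#' Plots an [aggregate_taxa()] table as per-sample stacked bars, with
#' `"Others"` and `"unclassified"` stacked last.
#'
#' @param composition A tibble from [aggregate_taxa()].
#' @return A ggplot.
#' @examples
#' ra <- relative_abundance(seaice_counts())
#' plot_composition(aggregate_taxa(ra, seaice_taxonomy(), rank = "genus"))
#' @export
plot_composition <- function(composition) {
  samples <- setdiff(names(composition), "taxon")
  long <- tidyr::pivot_longer(composition, dplyr::all_of(samples),
                              names_to = "sample_id", values_to = "percent")
  named <- setdiff(unique(composition$taxon), c("Others", "unclassified"))
  lev <- c(sort(named), intersect(c("Others", "unclassified"),
                                  composition$taxon))
  long$taxon <- factor(long$taxon, levels = rev(lev))
  long$sample_id <- factor(long$sample_id, levels = samples)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$percent,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-OTU contaminant load
#'
#' Bar chart of mean +/- sd relative abundance of each contaminant OTU
#' across the environmental samples, from a [contaminant_load()] result.
#'
#' @param object A `contaminant_load`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.contaminant_load <- function(object, ...) {
  d <- object$per_otu
  d$otu_id <- factor(d$otu_id, levels = d$otu_id[order(-d$mean_pct)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$otu_id, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_pct - .data$sd_pct, 0),
                   ymax = .data$mean_pct + .data$sd_pct),
      width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "Mean relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
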