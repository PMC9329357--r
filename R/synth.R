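#' Configuration for the synthetic-community generator
#'
#' The defaults emulate the structure of a low-biomass sea-ice monitoring
#' survey: 2 environmental ice cores, 3 interface-water samples, one
#' processing control and one DNA-extraction control; mean sequencing
#' depths of 23,000 (water), 21,000 (controls) and 9,000 (ice) read pairs
#' with Poisson depth noise; an environmental community of ~2,000 OTUs with
#' log-normal abundance weights; and 13 contaminant OTUs split 6 (PC-only),
#' 3 (DC-only), 4 (shared) that collectively reach only ~0.3% relative
#' abundance in environmental samples (the configured spill rate) while
#' dominating the controls via a low-concentration Dirichlet profile (few
#' dominant taxa -- the classic reagent-contamination signature of taxon
#' richness inversely correlated with bacterial load).
#'
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param n_env_otus Size of the environmental OTU pool.
#' @param n_contaminant_otus Number of planted contaminant OTUs.
#' @param n_ice,n_water,n_pc,n_dc Samples per role.
#' @param depth_water,depth_control,depth_ice Mean read depths per role.
#' @param env_lnorm_meanlog,env_lnorm_sdlog Log-normal parameters of the
#'   environmental OTU weights.
#' @param split Named integer vector `c(pc_only, dc_only, shared)`; must
#'   sum to `n_contaminant_otus`.
#' @param spill_rate Target total contaminant relative abundance per
#'   environmental sample (fraction, default 0.003 = 0.3%).
#' @param cross_contamination_rate Fraction of control reads leaking from
#'   the environmental community (default 0 = clean controls).
#' @param contaminant_dirichlet Dirichlet concentration of the
#'   within-control contaminant profile (small = few dominant taxa).
#' @param contaminant_dropout If `FALSE` (default) every planted
#'   contaminant is guaranteed >= 1 read in each of its designated
#'   controls; `TRUE` removes the guarantee for stress testing.
#' @return A validated `synth_config` list.
#' @examples
#' cfg <- synth_config(seed = 42, n_env_otus = 100)
#' @export
synth_config <- function(seed = 1L,
                         n_env_otus = 2000L,
                         n_contaminant_otus = 13L,
                         n_ice = 2L, n_water = 3L, n_pc = 1L, n_dc = 1L,
                         depth_water = 23000, depth_control = 21000,
                         depth_ice = 9000,
                         env_lnorm_meanlog = 0, env_lnorm_sdlog = 2,
                         split = c(pc_only = 6L, dc_only = 3L, shared = 4L),
                         spill_rate = 0.003,
                         cross_contamination_rate = 0,
                         contaminant_dirichlet = 0.3,
                         contaminant_dropout = FALSE) {
  cfg <- list(
    seed = as.integer(seed), n_env_otus = as.integer(n_env_otus),
    n_contaminant_otus = as.integer(n_contaminant_otus),
    n_ice = as.integer(n_ice), n_water = as.integer(n_water),
    n_pc = as.integer(n_pc), n_dc = as.integer(n_dc),
    depth_water = depth_water, depth_control = depth_control,
    depth_ice = depth_ice,
    env_lnorm_meanlog = env_lnorm_meanlog, env_lnorm_sdlog = env_lnorm_sdlog,
    split = split, spill_rate = spill_rate,
    cross_contamination_rate = cross_contamination_rate,
    contaminant_dirichlet = contaminant_dirichlet,
    contaminant_dropout = isTRUE(contaminant_dropout)
  )
  if (!setequal(names(split), c("pc_only", "dc_only", "shared")) ||
      sum(split) != cfg$n_contaminant_otus || any(split < 0)) {
    rlang::abort(
      "`split` must be c(pc_only, dc_only, shared) summing to `n_contaminant_otus`.",
      class = "cryoclean_config_error"
    )
  }
  rates <- c(cfg$spill_rate, cfg$cross_contamination_rate)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("rates must lie in [0, 1].", class = "cryoclean_config_error")
  }
  if (any(c(cfg$depth_water, cfg$depth_control, cfg$depth_ice) <= 0)) {
    rlang::abort("mean depths must be > 0.", class = "cryoclean_config_error")
  }
  if (cfg$spill_rate > 0 && cfg$n_contaminant_otus == 0) {
    rlang::abort("spill_rate > 0 needs at least one contaminant OTU.",
                 class = "cryoclean_config_error")
  }
  if (cfg$n_env_otus < 1) {
    rlang::abort("need at least one environmental OTU.",
                 class = "cryoclean_config_error")
  }
  class(cfg) <- "synth_config"
  cfg
}

rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

#' Generate a synthetic monitoring dataset with planted ground truth
#'
#' Draws an OTU count table, taxonomy, sample sheet and a `synthetic_truth`
#' record from a [synth_config()]. Environmental samples are multinomial
#' draws of Poisson-distributed depth from the log-normal environmental
#' community, with a binomial share of reads (expected fraction =
#' `spill_rate`) diverted to the planted contaminants; each control sample
#' draws from its designated contaminant set (PC: pc_only + shared, DC:
#' dc_only + shared) plus any configured cross-contamination leak from the
#' environmental community. Unless `contaminant_dropout` is set, every
#' planted contaminant is seeded with one read in each designated control
#' before the multinomial draw, so provenance recovery is exact by
#' construction. Environmental OTUs that receive no reads anywhere are
#' dropped (an observed OTU table has no all-zero rows); planted
#' contaminant rows are always kept.
#'
#' @param config A [synth_config()].
#' @return A list with `counts` ([otu_tbl()]), `taxonomy`
#'   ([taxonomy_tbl()]), `samples` ([sample_sheet()]) and `truth`
#'   (`synthetic_truth`: planted ids with provenance, expected contaminant
#'   fraction, realized depths, seed).
#' @examples
#' d <- generate_dataset(synth_config(seed = 7, n_env_otus = 50,
#'                                    depth_water = 500, depth_control = 500,
#'                                    depth_ice = 200))
#' glance(identify_contaminants(d$counts, d$samples))
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  env_ids <- sprintf("ENV_%04d", seq_len(cfg$n_env_otus))
  cont_ids <- character(0)
  provenance <- character(0)
  if (cfg$n_contaminant_otus > 0) {
    cont_ids <- sprintf("CONT_%02d", seq_len(cfg$n_contaminant_otus))
    provenance <- rep(c("pc_only", "dc_only", "shared"),
                      times = cfg$split[c("pc_only", "dc_only", "shared")])
  }
  pc_designated <- cont_ids[provenance %in% c("pc_only", "shared")]
  dc_designated <- cont_ids[provenance %in% c("dc_only", "shared")]

  env_w <- stats::rlnorm(cfg$n_env_otus, cfg$env_lnorm_meanlog,
                         cfg$env_lnorm_sdlog)
  env_w <- env_w / sum(env_w)
  spill_w <- if (length(cont_ids)) rdirichlet1(length(cont_ids), 1) else numeric(0)
  pc_w <- if (length(pc_designated))
    rdirichlet1(length(pc_designated), cfg$contaminant_dirichlet) else numeric(0)
  dc_w <- if (length(dc_designated))
    rdirichlet1(length(dc_designated), cfg$contaminant_dirichlet) else numeric(0)

  all_ids <- c(env_ids, cont_ids)
  sheet <- sample_sheet(tibble::tibble(
    sample_id = c(sprintf("Ice_%d", seq_len(cfg$n_ice)),
                  sprintf("Water_%d", seq_len(cfg$n_water)),
                  sprintf("PC_%d", seq_len(cfg$n_pc)),
                  sprintf("DC_%d", seq_len(cfg$n_dc))),
    role = rep(c("environmental_ice", "environmental_water",
                 "processing_control", "extraction_control"),
               times = c(cfg$n_ice, cfg$n_water, cfg$n_pc, cfg$n_dc)),
    replicate_group = rep(c("ice", "water", "processing_control",
                            "extraction_control"),
                          times = c(cfg$n_ice, cfg$n_water, cfg$n_pc, cfg$n_dc))
  ))

  counts <- matrix(0L, nrow = length(all_ids), ncol = nrow(sheet),
                   dimnames = list(all_ids, sheet$sample_id))
  depths <- integer(nrow(sheet))
  names(depths) <- sheet$sample_id

  draw_env_sample <- function(depth) {
    n_cont <- if (cfg$spill_rate > 0 && length(cont_ids))
      stats::rbinom(1L, depth, cfg$spill_rate) else 0L
    col <- stats::setNames(rep(0L, length(all_ids)), all_ids)
    if (depth - n_cont > 0) {
      col[env_ids] <- as.integer(stats::rmultinom(1L, depth - n_cont, env_w))
    }
    if (n_cont > 0) {
      col[cont_ids] <- col[cont_ids] +
        as.integer(stats::rmultinom(1L, n_cont, spill_w))
    }
    col
  }
  draw_control_sample <- function(depth, designated, w) {
    col <- stats::setNames(rep(0L, length(all_ids)), all_ids)
    guaranteed <- if (!cfg$contaminant_dropout) length(designated) else 0L
    depth <- max(depth, guaranteed)
    if (guaranteed > 0) col[designated] <- 1L
    rest <- depth - guaranteed
    if (rest > 0) {
      n_leak <- if (cfg$cross_contamination_rate > 0)
        stats::rbinom(1L, rest, cfg$cross_contamination_rate) else 0L
      n_cont <- rest - n_leak
      if (n_cont > 0 && length(designated)) {
        col[designated] <- col[designated] +
          as.integer(stats::rmultinom(1L, n_cont, w))
      }
      if (n_leak > 0) {
        col[env_ids] <- col[env_ids] +
          as.integer(stats::rmultinom(1L, n_leak, env_w))
      }
    }
    col
  }

  for (i in seq_len(nrow(sheet))) {
    role <- sheet$role[i]
    mean_depth <- switch(role,
      environmental_ice = cfg$depth_ice,
      environmental_water = cfg$depth_water,
      cfg$depth_control
    )
    depth <- stats::rpois(1L, mean_depth)
    col <- switch(role,
      environmental_ice = ,
      environmental_water = draw_env_sample(depth),
      processing_control = draw_control_sample(depth, pc_designated, pc_w),
      extraction_control = draw_control_sample(depth, dc_designated, dc_w)
    )
    counts[, i] <- col
    depths[i] <- sum(col)
  }

  observed <- rowSums(counts) > 0 | all_ids %in% cont_ids
  counts <- counts[observed, , drop = FALSE]
  tab <- otu_tbl(tibble::as_tibble(counts, rownames = "otu_id"))
  taxonomy <- synth_taxonomy(rownames(counts), cont_ids)
  truth <- structure(
    list(
      planted = tibble::tibble(otu_id = cont_ids, provenance = provenance),
      expected_contaminant_fraction = cfg$spill_rate,
      realized_depths = tibble::tibble(sample_id = sheet$sample_id,
                                       depth = unname(depths)),
      seed = cfg$seed
    ),
    class = "synthetic_truth"
  )
  list(counts = tab, taxonomy = taxonomy, samples = sheet, truth = truth)
}

env_genus_pool <- c("Polaribacter", "Colwellia", "Glaciecola", "Octadecabacter",
                    "Polaromonas", "Flavobacterium", "Psychrobacter",
                    "Shewanella", "Sulfitobacter", "Planktomarina",
                    "Nitrosopumilus", "Marinobacter")
kitome_genus_pool <- c("Acinetobacter", "Pseudomonas", "Corynebacterium",
                       "Stenotrophomonas", "Burkholderia", "Ralstonia",
                       "Methylobacterium", "Sphingomonas", "Cutibacterium",
                       "Staphylococcus", "Streptococcus", "Deinococcus")

synth_taxonomy <- function(ids, cont_ids) {
  is_cont <- ids %in% cont_ids
  genus <- character(length(ids))
  genus[!is_cont] <- sample(env_genus_pool, sum(!is_cont), replace = TRUE)
  genus[is_cont] <- sample(kitome_genus_pool, sum(is_cont), replace = TRUE)
  taxonomy_tbl(tibble::tibble(
    otu_id = ids,
    domain = "Bacteria",
    phylum = ifelse(is_cont, "Proteobacteria", "Bacteroidota"),
    genus = genus,
    confidence = round(stats::runif(length(ids), 0.75, 1), 3),
    organelle_flag = "none"
  ))
}

#' Score contaminant recovery against planted truth
#'
#' Set-overlap scores of an identified catalog against the generator's
#' planted contaminants: precision = |identified AND planted| /
#' |identified| (`NA` when nothing was identified), recall likewise over
#' the planted set, plus a per-OTU provenance confusion table.
#'
#' @param catalog An [identify_contaminants()] catalog.
#' @param truth The `truth` element of [generate_dataset()].
#' @return A one-row tibble with `precision`, `recall`, `n_identified`,
#'   `n_planted`, `n_correct`, `provenance_agreement` (fraction of
#'   correctly identified OTUs whose provenance label matches), and the
#'   confusion table in the `confusion` attribute.
#' @export
score_recovery <- function(catalog, truth) {
  stopifnot(inherits(catalog, "contaminant_catalog"),
            inherits(truth, "synthetic_truth"))
  identified <- catalog$contaminant_otu_ids
  planted <- truth$planted$otu_id
  correct <- intersect(identified, planted)
  confusion <- dplyr::full_join(
    tibble::tibble(otu_id = planted,
                   truth_provenance = truth$planted$provenance),
    tibble::tibble(otu_id = identified,
                   called_provenance = unname(catalog$provenance)),
    by = "otu_id"
  )
  agree <- confusion$truth_provenance == confusion$called_provenance
  out <- tibble::tibble(
    precision = if (length(identified)) length(correct) / length(identified)
                else NA_real_,
    recall = if (length(planted)) length(correct) / length(planted)
             else NA_real_,
    n_identified = length(identified),
    n_planted = length(planted),
    n_correct = length(correct),
    provenance_agreement = if (length(correct))
      mean(agree[!is.na(agree)]) else NA_real_
  )
  attr(out, "confusion") <- confusion
  out
}
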