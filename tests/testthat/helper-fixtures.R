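# Shared generators for property-style tests. All randomness is wrapped in
# withr::with_seed at the call site.

random_otu_tbl <- function(n_otu = 20, n_samp = 6, max_count = 50,
                           zero_prob = 0.5) {
  ids <- sprintf("OTU_%03d", seq_len(n_otu))
  samples <- sprintf("S%02d", seq_len(n_samp))
  m <- matrix(
    ifelse(stats::runif(n_otu * n_samp) < zero_prob, 0L,
           as.integer(sample.int(max_count, n_otu * n_samp, replace = TRUE))),
    nrow = n_otu, dimnames = list(ids, samples)
  )
  otu_tbl(tibble::as_tibble(m, rownames = "otu_id"))
}

# sheet assigning the last columns to control roles
random_sheet <- function(tab, n_pc = 1, n_dc = 1, n_ice = 2) {
  ids <- sample_ids(tab)
  n <- length(ids)
  stopifnot(n >= n_pc + n_dc + n_ice)
  n_water <- n - n_pc - n_dc - n_ice
  sample_sheet(tibble::tibble(
    sample_id = ids,
    role = rep(c("environmental_ice", "environmental_water",
                 "processing_control", "extraction_control"),
               times = c(n_ice, n_water, n_pc, n_dc)),
    replicate_group = rep(c("ice", "water", "pc", "dc"),
                          times = c(n_ice, n_water, n_pc, n_dc))
  ))
}

random_taxonomy <- function(tab, below_domain = character()) {
  ids <- otu_ids(tab)
  taxonomy_tbl(tibble::tibble(
    otu_id = ids,
    domain = "Bacteria",
    phylum = sample(c("Proteobacteria", "Bacteroidota"), length(ids), TRUE),
    genus = sample(c("Polaribacter", "Colwellia", "Acinetobacter"),
                   length(ids), TRUE),
    confidence = ifelse(ids %in% below_domain, 0.5,
                        round(stats::runif(length(ids), 0.75, 1), 3)),
    organelle_flag = "none"
  ))
}

small_synth_config <- function(seed = 1) {
  synth_config(seed = seed, n_env_otus = 80, depth_water = 2000,
               depth_control = 1500, depth_ice = 800)
}
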