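test_that("relative abundances normalise each sample to 100", {
  one <- relative_abundance(otu_tbl(data.frame(otu_id = "a", s1 = 7L)))
  expect_equal(one$s1, 100)
  two <- relative_abundance(otu_tbl(data.frame(otu_id = c("a", "b"),
                                               s1 = c(30L, 70L))))
  expect_equal(two$s1, c(30, 70))

  withr::with_seed(5, rand <- random_otu_tbl(25, 6, max_count = 40))
  ra <- relative_abundance(rand)
  m <- as.matrix(as.data.frame(rand)[, -1])
  for (s in colnames(m)) {
    tot <- sum(m[, s])
    if (tot > 0) {
      expect_equal(ra[[s]], 100 * m[, s] / tot, ignore_attr = TRUE)
      expect_equal(sum(ra[[s]]), 100, tolerance = 1e-9)
    }
  }
  expect_equal(unname(attr(ra, "denominators")), unname(colSums(m)))
})

test_that("zero-total samples are flagged as undefined, not fatal", {
  tab <- otu_tbl(data.frame(otu_id = c("a", "b"), s1 = c(2L, 2L), s2 = 0L))
  ra <- relative_abundance(tab)
  expect_identical(attr(ra, "undefined_samples"), "s2")
  expect_equal(ra$s2, c(0, 0))
})

test_that("contaminant load reproduces the published summary statistics", {
  cat <- identify_contaminants(seaice_counts(), seaice_samples())
  load <- contaminant_load(as_relabund(seaice_contaminant_abundance()),
                           cat, seaice_samples())
  # per-sample totals match the published row up to the rounding of the
  # published per-OTU cells (2 decimals each, 13 OTUs)
  expect_equal(load$per_sample$total_pct, c(0.25, 0.32, 0.12, 0.40, 0.61),
               tolerance = 0.12)
  # mean 0.3, sample sd (n-1) 0.2 at one decimal place, whether computed
  # from the published per-OTU values or from the published totals row
  expect_equal(round(load$mean_total_pct, 1), 0.3)
  expect_equal(round(mean(c(0.25, 0.32, 0.12, 0.40, 0.61)), 1), 0.3)
  expect_equal(round(load$sd_total_pct, 1), 0.2)
  otu25 <- tidy(load)[tidy(load)$otu_id == "OTU_25", ]
  expect_equal(round(otu25$mean_pct, 1), 0.1)
  expect_equal(otu25$sd_pct, 0.09, tolerance = 0.1) # published: 0.1 +/- 0.09
  # mean of per-sample totals and sum of per-OTU means agree
  expect_equal(mean(load$per_sample$total_pct), sum(tidy(load)$mean_pct))
})

test_that("all-zero contaminants give a zero load", {
  tab <- otu_tbl(data.frame(otu_id = c("a", "c"), E1 = c(10L, 0L),
                            E2 = c(10L, 0L), PCs = c(0L, 5L)))
  sheet <- sample_sheet(data.frame(
    sample_id = c("E1", "E2", "PCs"),
    role = c("environmental_water", "environmental_water",
             "processing_control")
  ))
  cat <- identify_contaminants(tab, sheet)
  load <- contaminant_load(relative_abundance(tab), cat, sheet)
  expect_equal(load$per_sample$total_pct, c(0, 0))
  expect_equal(load$mean_total_pct, 0)
  expect_equal(load$sd_total_pct, 0)
})

test_that("pooled presence sets are unions over member samples", {
  tab <- otu_tbl(data.frame(otu_id = c("only_ice2", "nowhere", "everywhere"),
                            Ice_1 = c(0L, 0L, 3L), Ice_2 = c(4L, 0L, 3L),
                            W1 = c(0L, 0L, 3L), PCs = c(0L, 0L, 1L)))
  sheet <- sample_sheet(data.frame(
    sample_id = c("Ice_1", "Ice_2", "W1", "PCs"),
    role = c("environmental_ice", "environmental_ice", "environmental_water",
             "processing_control"),
    replicate_group = c("ice", "ice", "water", NA)
  ))
  sets <- pool_presence(tab, sheet)
  expect_true("only_ice2" %in% sets$ice)
  expect_false("only_ice2" %in% sets$water)
  expect_false("nowhere" %in% unlist(sets))
  expect_true(all(c("ice", "water", "processing_control") %in% names(sets)))

  withr::with_seed(8, rand <- random_otu_tbl(20, 6, max_count = 5))
  rsheet <- random_sheet(rand)
  rsets <- pool_presence(rand, rsheet)
  m <- as.matrix(as.data.frame(rand)[, -1]) >= 1
  rownames(m) <- rand$otu_id
  for (grp in unique(rsheet$replicate_group[startsWith(rsheet$role, "env")])) {
    ids <- rsheet$sample_id[rsheet$replicate_group == grp]
    oracle <- rownames(m)[rowSums(m[, ids, drop = FALSE]) > 0]
    expect_setequal(rsets[[grp]], oracle)
  }
})

test_that("venn partitions enumerate every region and sum to the union", {
  v <- venn_partition(list(PC = letters[1:10], DC = letters[7:13]))
  t2 <- tidy(v)
  expect_identical(t2$size[t2$region == "PC"], 6L)
  expect_identical(t2$size[t2$region == "DC"], 3L)
  expect_identical(t2$size[t2$region == "PC&DC"], 4L)
  expect_identical(sum(t2$size), 13L)

  disj <- tidy(venn_partition(list(A = c("x", "y"), B = c("z"))))
  expect_identical(disj$size[disj$region == "A&B"], 0L)

  expect_error(venn_partition(list(a = "x")), class = "cryoclean_arity_error")
  expect_error(venn_partition(list(a = "x", b = "y", c = "z", d = "w")),
               class = "cryoclean_arity_error")

  # random 3-set instances against per-element brute-force region assignment
  withr::with_seed(13, {
    for (i in 1:25) {
      sets <- list(A = sample(letters, sample(0:15, 1)),
                   B = sample(letters, sample(0:15, 1)),
                   C = sample(letters, sample(0:15, 1)))
      tv <- tidy(venn_partition(sets))
      expect_identical(nrow(tv), 7L)
      expect_identical(sum(tv$size), length(unique(unlist(sets))))
      for (el in unique(unlist(sets))) {
        pattern <- vapply(sets, function(s) el %in% s, logical(1))
        row <- tv[tv$in_A == pattern[["A"]] & tv$in_B == pattern[["B"]] &
                    tv$in_C == pattern[["C"]], ]
        expect_gte(row$size, 1L)
      }
    }
  })
})

test_that("taxon aggregation applies the strict 0.5% Others rule and groups unclassified", {
  tab <- otu_tbl(data.frame(
    otu_id = c("a", "b", "c", "d"),
    s1 = c(9895L, 50L, 4L, 51L), s2 = c(10000L, 0L, 0L, 0L)
  ))
  tax <- taxonomy_tbl(tibble::tibble(
    otu_id = c("a", "b", "c", "d"),
    domain = "Bacteria",
    genus = c("Dominant", "Boundary", "Rare", "LowConf"),
    confidence = c(0.95, 0.95, 0.95, 0.5)
  ))
  ra <- relative_abundance(tab)
  comp <- aggregate_taxa(ra, tax, rank = "genus")
  # taxon at exactly 0.50% in one sample is retained (merge is strict "<")
  expect_true("Boundary" %in% comp$taxon)
  expect_true("Others" %in% comp$taxon) # "Rare" at 0.04%
  expect_false("Rare" %in% comp$taxon)
  # below-70%-confidence OTU grouped under unclassified
  expect_true("unclassified" %in% comp$taxon)
  expect_false("LowConf" %in% comp$taxon)
  expect_equal(sum(comp$s1), 100, tolerance = 1e-9)
  expect_equal(sum(comp$s2), 100, tolerance = 1e-9)

  # single-genus table: one row at 100%, no Others
  single <- aggregate_taxa(
    relative_abundance(otu_tbl(data.frame(otu_id = "a", s1 = 5L))),
    taxonomy_tbl(tibble::tibble(otu_id = "a", genus = "Solo",
                                confidence = 1)),
    rank = "genus"
  )
  expect_identical(single$taxon, "Solo")
  expect_equal(single$s1, 100)

  # random tables match a brute-force group-by-rank summation oracle
  withr::with_seed(19, {
    rand <- random_otu_tbl(30, 4, max_count = 50, zero_prob = 0.2)
    rtax <- random_taxonomy(rand)
    rra <- relative_abundance(rand)
    comp2 <- aggregate_taxa(rra, rtax, rank = "genus", others_threshold = 0)
    # with threshold 0 nothing merges: compare against plain group sums
    df <- as.data.frame(rra)
    df$genus <- rtax$genus[match(df$otu_id, rtax$otu_id)]
    for (g in unique(df$genus)) {
      expect_equal(
        unlist(comp2[comp2$taxon == g, -1]),
        colSums(df[df$genus == g, sample_ids(rand)]),
        ignore_attr = TRUE
      )
    }
  })
})
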