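test_that("presence calls equal the elementwise threshold oracle", {
  tab <- otu_tbl(data.frame(otu_id = c("a", "b"), s1 = c(0L, 1L),
                            s2 = c(4L, 5L)))
  p1 <- call_presence(tab)
  expect_identical(p1$s1, c(FALSE, TRUE)) # 0 absent, 1 present at default
  p5 <- call_presence(tab, min_reads = 5)
  expect_identical(p5$s2, c(FALSE, TRUE)) # 4 absent at threshold 5

  withr::with_seed(3, rand <- random_otu_tbl(30, 4, max_count = 10))
  for (mr in c(1L, 3L, 7L)) {
    pres <- call_presence(rand, mr)
    m <- as.matrix(as.data.frame(rand)[, -1])
    expect_identical(unname(as.matrix(pres[, -1])), unname(m >= mr))
  }
  expect_error(call_presence(tab, 0), class = "cryoclean_argument_error")
})

test_that("the contaminant catalog of the bundled survey has the expected structure", {
  cat <- identify_contaminants(seaice_counts(), seaice_samples())
  g <- glance(cat)
  expect_identical(g$n_contaminants, 13L)
  expect_identical(g$n_pc, 10L)
  expect_identical(g$n_dc, 7L)
  expect_identical(g$n_shared, 4L)
  expect_identical(g$n_pc_minus_dc, 6L)
  expect_identical(length(pc_minus_dc(cat)), 6L)
  expect_setequal(cat$provenance[c("OTU_4", "OTU_5", "OTU_19", "OTU_63")],
                  "shared")
})

test_that("provenance assignment follows control roles", {
  # an OTU present only in the extraction control is dc_only
  tab <- otu_tbl(data.frame(otu_id = c("env1", "dc_otu", "pc_otu"),
                            E1 = c(50L, 0L, 0L), PCs = c(0L, 0L, 12L),
                            DCs = c(0L, 12L, 0L)))
  sheet <- sample_sheet(data.frame(
    sample_id = c("E1", "PCs", "DCs"),
    role = c("environmental_water", "processing_control", "extraction_control")
  ))
  cat <- identify_contaminants(tab, sheet)
  expect_identical(unname(cat$provenance["dc_otu"]), "dc_only")
  expect_identical(unname(cat$provenance["pc_otu"]), "pc_only")
  expect_false("env1" %in% cat$contaminant_otu_ids)

  # all-zero controls -> empty catalog
  clean <- otu_tbl(data.frame(otu_id = "x", E1 = 9L, PCs = 0L, DCs = 0L))
  expect_warning(cat0 <- identify_contaminants(clean, sheet), "zero total")
  expect_identical(length(cat0$contaminant_otu_ids), 0L)

  # no controls -> refusal
  env_only <- sample_sheet(data.frame(sample_id = c("E1", "PCs", "DCs"),
                                      role = "environmental_water"))
  expect_error(identify_contaminants(tab, env_only),
               class = "cryoclean_no_controls_error")
})

test_that("pc_minus_dc equals the brute-force set difference", {
  cat <- identify_contaminants(seaice_counts(), seaice_samples())
  expect_setequal(pc_minus_dc(cat), setdiff(cat$pc_set, cat$dc_set))
  expect_identical(length(cat$pc_minus_dc_set),
                   length(cat$pc_set) - length(intersect(cat$pc_set, cat$dc_set)))

  # full overlap -> empty difference
  tab <- otu_tbl(data.frame(otu_id = "x", E1 = 1L, PCs = 5L, DCs = 5L))
  sheet <- sample_sheet(data.frame(
    sample_id = c("E1", "PCs", "DCs"),
    role = c("environmental_water", "processing_control", "extraction_control")
  ))
  expect_identical(pc_minus_dc(identify_contaminants(tab, sheet)), character(0))
})

test_that("environmental overlap partitions the bundled contaminants as 2/2/3", {
  cat <- identify_contaminants(seaice_counts(), seaice_samples())
  rep <- environmental_overlap(cat, seaice_counts(), seaice_samples())
  g <- glance(rep)
  expect_identical(g$n_in_env, 7L)
  expect_identical(g$ice_only, 2L)
  expect_identical(g$water_only, 2L)
  expect_identical(g$both, 3L)
  expect_identical(g$neither, 6L)
  d <- tidy(rep)
  expect_setequal(d$otu_id[d$category == "ice_only"], c("OTU_4", "OTU_5"))
  expect_setequal(d$otu_id[d$category == "water_only"], c("OTU_36", "OTU_98"))
  expect_setequal(d$otu_id[d$category == "both"],
                  c("OTU_19", "OTU_25", "OTU_1153"))
})

test_that("contaminants below min_reads in the environment count as neither", {
  tab <- otu_tbl(data.frame(otu_id = "c1", I1 = 2L, W1 = 3L, PCs = 50L))
  sheet <- sample_sheet(data.frame(
    sample_id = c("I1", "W1", "PCs"),
    role = c("environmental_ice", "environmental_water", "processing_control")
  ))
  cat <- identify_contaminants(tab, sheet, min_reads = 5)
  rep <- environmental_overlap(cat, tab, sheet)
  expect_identical(glance(rep)$neither, 1L)

  # empty catalog -> all-zero report
  empty_cat <- identify_contaminants(
    otu_tbl(data.frame(otu_id = "c1", I1 = 2L, W1 = 3L, PCs = 1L)),
    sheet, min_reads = 5
  )
  g0 <- glance(environmental_overlap(empty_cat, tab, sheet))
  expect_identical(g0$n_contaminants, 0L)
  expect_identical(g0$n_in_env + g0$neither, 0L)
})

test_that("catalog invariants hold and min_reads is monotone on random tables", {
  withr::with_seed(99, {
    for (i in 1:50) {
      tab <- random_otu_tbl(sample(5:25, 1), sample(5:8, 1), max_count = 8)
      sheet <- random_sheet(tab)
      prev <- NULL
      for (mr in c(1L, 2L, 4L)) {
        cat <- suppressWarnings(identify_contaminants(tab, sheet, min_reads = mr))
        # set algebra invariants
        expect_setequal(cat$contaminant_otu_ids, union(cat$pc_set, cat$dc_set))
        expect_setequal(cat$pc_minus_dc_set, setdiff(cat$pc_set, cat$dc_set))
        g <- glance(cat)
        expect_identical(g$n_pc_only + g$n_dc_only + g$n_shared,
                         g$n_contaminants)
        # raising min_reads never enlarges the catalog
        if (!is.null(prev)) {
          expect_true(all(cat$contaminant_otu_ids %in% prev))
        }
        prev <- cat$contaminant_otu_ids
      }
    }
  })
})
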