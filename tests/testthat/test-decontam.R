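seaice_catalog <- function() {
  identify_contaminants(seaice_counts(), seaice_samples())
}

test_that("conservative strategy removes every catalogued OTU from the environmental table", {
  res <- decontaminate_conservative(seaice_counts(), seaice_catalog(),
                                    seaice_samples())
  expect_identical(nrow(res$cleaned), 0L) # all 13 OTUs here are contaminants
  expect_setequal(sample_ids(res$cleaned),
                  c("Ice_1", "Ice_2", "Water_1", "Water_2", "Water_3"))
  g <- glance(res)
  expect_equal(g$reads_after + g$reads_removed, g$reads_before)
  expect_equal(g$reads_removed, 19 + 35 + 30 + 89 + 154)
})

test_that("empty catalog leaves the environmental table untouched", {
  tab <- otu_tbl(data.frame(otu_id = c("a", "b"), E1 = c(3L, 4L),
                            PCs = c(0L, 0L), DCs = c(0L, 0L)))
  sheet <- sample_sheet(data.frame(
    sample_id = c("E1", "PCs", "DCs"),
    role = c("environmental_water", "processing_control", "extraction_control")
  ))
  cat <- suppressWarnings(identify_contaminants(tab, sheet))
  res <- decontaminate_conservative(tab, cat, sheet)
  expect_identical(otu_ids(res$cleaned), c("a", "b"))
  expect_identical(sample_ids(res$cleaned), "E1")
  expect_identical(res$reads_removed, 0L)
})

test_that("conservative removal matches a brute-force row-drop oracle on random tables", {
  withr::with_seed(17, {
    for (i in 1:20) {
      tab <- random_otu_tbl(15, 6, max_count = 20)
      sheet <- random_sheet(tab)
      cat <- suppressWarnings(identify_contaminants(tab, sheet))
      res <- decontaminate_conservative(tab, cat, sheet)
      env_ids <- sheet$sample_id[startsWith(sheet$role, "environmental")]
      oracle <- tab[!tab$otu_id %in% cat$contaminant_otu_ids,
                    c("otu_id", env_ids)]
      expect_identical(as.data.frame(res$cleaned), as.data.frame(oracle))
    }
  })
})

test_that("control-abundance threshold strategy matches a per-column proportion oracle", {
  withr::with_seed(23, {
    for (i in 1:15) {
      tab <- random_otu_tbl(15, 6, max_count = 20)
      sheet <- random_sheet(tab)
      cat <- suppressWarnings(identify_contaminants(tab, sheet))
      res <- suppressWarnings(
        decontaminate_by_control_abundance(tab, cat, sheet, threshold = 5)
      )
      # brute-force recomputation of control percentages
      ctrl <- sheet$sample_id[sheet$role %in%
                                c("processing_control", "extraction_control")]
      m <- as.matrix(as.data.frame(tab)[, ctrl, drop = FALSE])
      rownames(m) <- tab$otu_id
      pct <- sweep(m, 2, colSums(m), "/") * 100
      pct[, colSums(m) == 0] <- NA
      oracle <- intersect(
        cat$contaminant_otu_ids,
        rownames(pct)[apply(pct, 1, function(v) any(v > 5, na.rm = TRUE))]
      )
      expect_setequal(res$removed_otu_ids, oracle)
    }
  })
})

test_that("degenerate thresholds bracket the strategy family", {
  tab <- seaice_counts(); sheet <- seaice_samples(); cat <- seaice_catalog()
  cons <- decontaminate_conservative(tab, cat, sheet)
  at0 <- decontaminate_by_control_abundance(tab, cat, sheet, threshold = 0)
  expect_setequal(at0$removed_otu_ids, cons$removed_otu_ids)
  at100 <- decontaminate_by_control_abundance(tab, cat, sheet, threshold = 100)
  expect_identical(length(at100$removed_otu_ids), 0L)
  topall <- decontaminate_high_abundance(tab, cat, sheet,
                                         top_k = length(cat$contaminant_otu_ids))
  expect_setequal(topall$removed_otu_ids, cons$removed_otu_ids)
  expect_warning(
    over <- decontaminate_high_abundance(tab, cat, sheet, top_k = 99),
    "catalog size"
  )
  expect_setequal(over$removed_otu_ids, cons$removed_otu_ids)
})

test_that("top-k strategy matches a sort-and-slice oracle with lexicographic ties", {
  tab <- seaice_counts(); sheet <- seaice_samples(); cat <- seaice_catalog()
  top1 <- decontaminate_high_abundance(tab, cat, sheet, top_k = 1)
  # OTU_4 has the highest mean control abundance (24.7% in PC, 46.1% in DC)
  expect_identical(top1$removed_otu_ids, "OTU_4")

  withr::with_seed(31, {
    for (i in 1:15) {
      rtab <- random_otu_tbl(12, 6, max_count = 20)
      rsheet <- random_sheet(rtab)
      rcat <- suppressWarnings(identify_contaminants(rtab, rsheet))
      if (length(rcat$contaminant_otu_ids) < 2) next
      k <- sample(seq_along(rcat$contaminant_otu_ids), 1)
      res <- suppressWarnings(
        decontaminate_high_abundance(rtab, rcat, rsheet, top_k = k)
      )
      ctrl <- rsheet$sample_id[rsheet$role %in%
                                 c("processing_control", "extraction_control")]
      m <- as.matrix(as.data.frame(rtab)[, ctrl, drop = FALSE])
      rownames(m) <- rtab$otu_id
      pct <- sweep(m, 2, colSums(m), "/") * 100
      pct[, colSums(m) == 0] <- NA
      means <- rowMeans(pct, na.rm = TRUE)[rcat$contaminant_otu_ids]
      means[is.nan(means)] <- 0
      ord <- order(-means, names(means))
      oracle <- names(means)[ord][seq_len(k)]
      expect_identical(sort(res$removed_otu_ids), sort(oracle))
    }
  })
})

test_that("ratio strategy removes control-skewed OTUs and matches a mean-proportion oracle", {
  # 5% in controls vs 0.01% in env -> removed; 0.1% vs 2% -> retained
  tab <- otu_tbl(data.frame(
    otu_id = c("skewed", "env_dom", "filler"),
    E1 = c(1L, 200L, 9799L), E2 = c(1L, 200L, 9799L),
    PCs = c(50L, 1L, 949L), DCs = c(50L, 1L, 949L)
  ))
  sheet <- sample_sheet(data.frame(
    sample_id = c("E1", "E2", "PCs", "DCs"),
    role = c("environmental_water", "environmental_water",
             "processing_control", "extraction_control")
  ))
  cat <- identify_contaminants(tab, sheet)
  res <- decontaminate_by_ratio(tab, cat, sheet)
  expect_true("skewed" %in% res$removed_otu_ids)
  expect_false("env_dom" %in% res$removed_otu_ids)

  withr::with_seed(41, {
    for (i in 1:15) {
      rtab <- random_otu_tbl(12, 6, max_count = 20)
      rsheet <- random_sheet(rtab)
      rcat <- suppressWarnings(identify_contaminants(rtab, rsheet))
      res <- suppressWarnings(decontaminate_by_ratio(rtab, rcat, rsheet))
      ctrl <- rsheet$sample_id[rsheet$role %in%
                                 c("processing_control", "extraction_control")]
      env <- rsheet$sample_id[startsWith(rsheet$role, "environmental")]
      pmat <- function(ids) {
        m <- as.matrix(as.data.frame(rtab)[, ids, drop = FALSE])
        rownames(m) <- rtab$otu_id
        p <- sweep(m, 2, colSums(m), "/") * 100
        p[, colSums(m) == 0] <- NA
        p
      }
      cm <- rowMeans(pmat(ctrl), na.rm = TRUE); cm[is.nan(cm)] <- 0
      em <- rowMeans(pmat(env), na.rm = TRUE); em[is.nan(em)] <- 0
      oracle <- rcat$contaminant_otu_ids[
        cm[rcat$contaminant_otu_ids] > em[rcat$contaminant_otu_ids]
      ]
      expect_setequal(res$removed_otu_ids, oracle)
    }
  })
})

test_that("every strategy removes only catalogued OTUs and is nested in conservative", {
  withr::with_seed(53, {
    for (i in 1:10) {
      tab <- random_otu_tbl(15, 6, max_count = 25)
      sheet <- random_sheet(tab)
      cat <- suppressWarnings(identify_contaminants(tab, sheet))
      cons <- decontaminate_conservative(tab, cat, sheet)
      results <- suppressWarnings(list(
        cons,
        decontaminate_by_control_abundance(tab, cat, sheet, threshold = 10),
        if (length(cat$contaminant_otu_ids) >= 1)
          decontaminate_high_abundance(tab, cat, sheet, top_k = 1),
        decontaminate_by_ratio(tab, cat, sheet)
      ))
      for (res in Filter(Negate(is.null), results)) {
        expect_true(all(res$removed_otu_ids %in% cat$contaminant_otu_ids))
        expect_true(all(res$removed_otu_ids %in% cons$removed_otu_ids))
        # ledger conservation per sample
        led <- tidy(res)
        per_sample_removed <- tapply(led$reads_removed, led$sample_id, sum)
        env_ids <- sheet$sample_id[startsWith(sheet$role, "environmental")]
        before <- sample_totals(tab)[env_ids]
        after <- sample_totals(res$cleaned)[env_ids]
        expect_equal(before - after,
                     as.numeric(per_sample_removed[env_ids]),
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("a catalog referencing unknown OTUs is rejected", {
  cat <- seaice_catalog()
  tab <- seaice_counts()[-1, ]
  expect_error(decontaminate_conservative(otu_tbl(tab), cat, seaice_samples()),
               "unknown", class = "cryoclean_format_error")
})
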