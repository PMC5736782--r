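test_that("packaged descriptor table loads with the published panel", {
  tab1 <- load_descriptor_table("table1")
  expect_s3_class(tab1, "descriptor_matrix")
  expect_equal(nrow(tab1), 18L)
  expect_equal(sum(tab1$group == "A"), 8L)
  expect_equal(sum(tab1$group == "B"), 10L)
  acr <- tab1[tab1$name == "acrivastine", descriptor_names()]
  expect_equal(unname(unlist(acr)),
               c(2.03, 4.55, 0.59, 1.50, 1, 4, 5, 6, 2.81, 2.07, 53, 348,
                 2.10))
  # hydrogen-bond bookkeeping holds on every row
  expect_true(all(tab1$hb_total == tab1$hbd + tab1$hba))
})

test_that("assay tables load with the published values", {
  tab2 <- load_assay_table("table2", "iam_mlv")
  expect_equal(nrow(tab2), 18L)
  dig <- tab2[tab2$name == "digoxin", ]
  expect_equal(dig$logk_iam, 0.92)
  expect_equal(dig$mlv_partitioning, 0.30)

  tab3 <- load_assay_table("table3", "ussing_papp")
  expect_equal(nrow(tab3), 18L)
  dig3 <- tab3[tab3$name == "digoxin", ]
  expect_equal(dig3$papp_wt_e6, 6.04)
  expect_equal(dig3$papp_ko_e6, 20.94)
})

test_that("fixture transcriptions are unchanged (checksums)", {
  sums <- tools::md5sum(c(pgplung_fixture("table1"),
                          pgplung_fixture("table2"),
                          pgplung_fixture("table3")))
  expect_equal(unname(sums),
               c("7d71eba98eedaac47418a95d38f1518a",
                 "439d5136cbc5d73feaf54516f5163790",
                 "3d23db90ac9dc45d6ba6aba6fed17f0f"))
})

test_that("schema violations raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_descriptor_table(empty), class = "pgplung_schema_error")

  tab1 <- as.data.frame(load_descriptor_table("table1"))
  # missing descriptor column
  broken <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab1[, setdiff(names(tab1), "psa")], broken, row.names = FALSE)
  expect_error(load_descriptor_table(broken), "psa")
  # duplicate compound name
  dup <- tab1; dup$name[2L] <- dup$name[1L]
  dup_f <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, dup_f, row.names = FALSE)
  expect_error(load_descriptor_table(dup_f), "duplicate")
  # non-numeric cell
  bad <- tab1; bad$mw <- as.character(bad$mw); bad$mw[3L] <- "n/a"
  bad_f <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, bad_f, row.names = FALSE)
  expect_error(load_descriptor_table(bad_f), "mw")
  # broken hydrogen-bond bookkeeping is caught, naming the row
  off <- tab1; off$hb_total[5L] <- off$hb_total[5L] + 1L
  off_f <- withr::local_tempfile(fileext = ".csv")
  write.csv(off, off_f, row.names = FALSE)
  expect_error(load_descriptor_table(off_f), off$name[5L])

  # a membrane-affinity file does not satisfy the permeability schema
  expect_error(load_assay_table("table2", "ussing_papp"),
               class = "pgplung_schema_error")
  expect_error(load_assay_table("table2", "no_such_kind"))
})

test_that("write/read round trip preserves full precision", {
  for (spec in list(c("table2", "iam_mlv"), c("table3", "ussing_papp"))) {
    tab <- load_assay_table(spec[1L], spec[2L])
    tab[[3L]] <- tab[[3L]] + pi * 1e-9   # exercise non-terminating digits
    f <- withr::local_tempfile(fileext = ".csv")
    write_table_csv(tab, f)
    back <- load_assay_table(f, spec[2L])
    expect_equal(back, tab)
  }
  tab1 <- load_descriptor_table("table1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tab1, f)
  expect_equal(load_descriptor_table(f), tab1)
})

test_that("analysis_config validates fields and loads from YAML", {
  cfg <- analysis_config()
  expect_s3_class(cfg, "analysis_config")
  expect_error(analysis_config(reservoir_volume_mL = -1), "positive")
  expect_error(analysis_config(sample_volume_mL = 11), "smaller")
  expect_error(analysis_config(folds = 1), "folds")
  expect_error(analysis_config(n_orth = -2), "n_orth")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reservoir_volume_mL: 12", "folds: 9", "n_orth: 2"), yml)
  cfg2 <- read_analysis_config(yml)
  expect_equal(cfg2$reservoir_volume_mL, 12)
  expect_equal(cfg2$folds, 9L)
  expect_equal(cfg2$n_orth, 2)
  writeLines("no_such_field: 1", yml)
  expect_error(read_analysis_config(yml), "unknown")
})

test_that("full analysis report reproduces the headline table values", {
  rep <- run_full_analysis()
  expect_equal(unlist(rep$oplsda$misclassified), "acrivastine")
  expect_equal(round(rep$membrane_affinity$logk_iam_mean$A, 2), 1.17)
  expect_equal(round(rep$membrane_affinity$mlv_mean$B, 2), 0.89)
  # leave-one-out folds run without error
  rep_loo <- run_full_analysis(analysis_config(folds = 18))
  expect_true(is.numeric(rep_loo$oplsda$q2))
})

test_that("report generation is deterministic (byte-identical JSON)", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_full_analysis(out_dir = d1)
  run_full_analysis(out_dir = d2)
  expect_identical(readBin(file.path(d1, "report.json"), "raw", 1e6),
                   readBin(file.path(d2, "report.json"), "raw", 1e6))
})
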