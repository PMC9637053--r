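make_cohort_df <- function(...) {
  validate_cohort_table(data.frame(..., stringsAsFactors = FALSE))
}

test_that("stratification splits follow the study cut-offs", {
  tab <- make_cohort_df(
    subject_id = sprintf("s%d", 1:4), group = rep("patient", 4),
    pfirrmann = c(2, 3, 4, 5), vas = c(7, 6, 8, 2))
  pg <- stratify(tab, stratification_rule("pfirrmann"))
  expect_setequal(pg$A, c("s3", "s4"))   # grade > 3
  expect_setequal(pg$B, c("s1", "s2"))   # grade <= 3

  vas <- stratify(make_cohort_df(subject_id = c("a", "b"),
                                 group = rep("patient", 2), vas = c(7, 6)),
                  stratification_rule("vas"))
  expect_equal(vas$A, "a")               # VAS > 6
  expect_equal(vas$B, "b")

  grp <- stratify(make_cohort_df(subject_id = c("p1", "c1", "c2"),
                                 group = c("patient", "control", "control")),
                  stratification_rule("group"))
  expect_equal(grp$A, "p1")

  cep <- stratify(make_cohort_df(subject_id = c("x", "y"),
                                 group = rep("patient", 2),
                                 cep_damage = c(TRUE, FALSE)),
                  stratification_rule("cep_damage"))
  expect_equal(cep$A, "x")
})

test_that("subgroup sizes sum to the non-missing count, with exclusions logged", {
  tab <- make_cohort_df(
    subject_id = sprintf("s%d", 1:6), group = rep("patient", 6),
    vas = c(7, 2, NA, 8, NA, 5))
  expect_message(sp <- stratify(tab, stratification_rule("vas")),
                 "excluded 2")
  expect_equal(length(sp$A) + length(sp$B), 4)
  expect_equal(sp$n_excluded, 2)
})

test_that("rules failing to split raise errors naming the rule", {
  ctl <- make_cohort_df(subject_id = c("c1", "c2"),
                        group = rep("control", 2), cep_damage = c(TRUE, TRUE))
  # patient-only restriction on an all-control cohort
  expect_error(stratify(ctl, stratification_rule("cep_damage",
                                                 name = "cep-in-patients",
                                                 within = list(group = "patient"))),
               "cep-in-patients")
  expect_error(stratify(ctl, stratification_rule("group")), "group")
})

test_that("run_analysis produces the full per-muscle report deterministically", {
  tc <- tiny_cohort(seed = 21)
  cfg <- list(data_dir = tc$dir, seed = 21)
  rep1 <- run_analysis(cfg)
  expect_s3_class(rep1, "fatmap_report")
  expect_setequal(names(rep1$results), FATMAP_MUSCLES)
  for (m in FATMAP_MUSCLES) {
    r <- rep1$results[[m]]$group
    expect_s3_class(r$spm, "spm_result")
    expect_length(r$overall, 5)
    expect_equal(unname(r$spm$group_sizes), c(4, 4))
  }
  expect_equal(nrow(rep1$results$multifidus$peaks), 8)

  # per-group mean curve equals the node-wise mean of member profiles
  ex <- rep1$extracted$multifidus
  idsA <- rep1$results$multifidus$group$subjects$A
  expect_equal(rep1$results$multifidus$group$mean_curve_A,
               colMeans(do.call(rbind,
                 lapply(ex$profiles[idsA], `[[`, "fi"))),
               tolerance = 1e-9)

  # reruns write byte-identical artifacts
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  write_report(rep1, o1, cfg)
  write_report(run_analysis(cfg), o2, cfg)
  for (f in c("profiles.csv", "peaks.csv", "spm_multifidus_group.json",
              "manifest.json"))
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)))
})

test_that("subjects with an unusable mask are dropped for that muscle only", {
  tc <- tiny_cohort(seed = 31)
  # blank one subject's multifidus mask on disk
  mp <- file.path(tc$dir, "sub-001", "mask_multifidus.nii")
  img <- RNifti::readNifti(mp)
  img[] <- 0
  RNifti::writeNifti(img, mp, datatype = "uint8")
  msgs <- capture_messages(ex <- extract_profiles(tc$gen$cohort, tc$dir))
  expect_true(any(grepl("sub-001", msgs)))
  expect_false("sub-001" %in% ex$multifidus$subjects)
  expect_true("sub-001" %in% ex$erector_spinae$subjects)
  expect_true("sub-001" %in% ex$psoas$subjects)
})

test_that("a YAML config file drives the same analysis", {
  tc <- tiny_cohort(seed = 41)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(data_dir = tc$dir, alpha = 0.05, n_nodes = 101,
                        seed = 41), yml)
  rep <- run_analysis(yml)
  expect_s3_class(rep, "fatmap_report")
  expect_equal(rep$settings$alpha, 0.05)
})
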