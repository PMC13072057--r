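test_that("default-size cohort: 20 patients, 120 conditions, 15 male, seed-reproducible", {
  cfg <- cohort_config(seed = 101, ptv_bin_width = 0.005)  # default counts, coarser PTV grid
  co <- generate_cohort(cfg)
  expect_length(co$patients, 20)
  sexes <- vapply(co$patients, `[[`, "", "sex")
  expect_equal(sum(sexes == "male"), 15)
  expect_equal(sum(sexes == "female"), 5)
  expect_equal(sum(vapply(co$patients, function(p) length(p$conditions), 0L)), 120)
  expect_setequal(names(co$patients[[1]]$conditions),
                  c(t(outer(c("IMRT", "IMPT"), c("conv", "bvs90", "bvs80"), paste, sep = "_"))))

  co2 <- generate_cohort(cfg)
  expect_identical(vapply(co$patients, `[[`, "", "sex"),
                   vapply(co2$patients, `[[`, "", "sex"))
  expect_identical(co$patients[[3]]$conditions$IMRT_conv$organ_dvhs$brain$volume,
                   co2$patients[[3]]$conditions$IMRT_conv$organ_dvhs$brain$volume)
  rm(co, co2); gc(FALSE)
})

test_that("vessel mean-dose scaling is exact per patient and modality; IMPT shrinks the bath", {
  co <- generate_cohort(cohort_config(n_patients = 5, seed = 7, ptv_bin_width = 0.005,
                                      include_overlap_outlier = FALSE))
  for (p in co$patients) {
    for (mod in c("IMRT", "IMPT")) {
      conv <- vessel_mean_dose(p$conditions[[paste0(mod, "_conv")]])
      b90 <- vessel_mean_dose(p$conditions[[paste0(mod, "_bvs90")]])
      b80 <- vessel_mean_dose(p$conditions[[paste0(mod, "_bvs80")]])
      expect_lt(abs(b90 / conv - 0.9), 0.005 * 0.9)
      expect_lt(abs(b80 / conv - 0.8), 0.005 * 0.8)
    }
    # proton low-dose bath: out-of-field organs shrink, vessels do not
    imrt <- p$conditions$IMRT_conv$organ_dvhs
    impt <- p$conditions$IMPT_conv$organ_dvhs
    expect_equal(mean_dose(impt$skeletal_muscle) / mean_dose(imrt$skeletal_muscle),
                 0.55, tolerance = 1e-6)
    expect_equal(mean_dose(impt$large_veins), mean_dose(imrt$large_veins))
  }
  # redistribution: brain dose up, esophagus down under vessel sparing
  p1 <- co$patients[[1]]
  expect_gt(mean_dose(p1$conditions$IMRT_bvs80$organ_dvhs$brain),
            mean_dose(p1$conditions$IMRT_conv$organ_dvhs$brain))
  expect_lt(mean_dose(p1$conditions$IMRT_bvs80$organ_dvhs$esophagus),
            mean_dose(p1$conditions$IMRT_conv$organ_dvhs$esophagus))
})

test_that("PTV DVHs meet the coverage bands and the HI envelope; volumes are per-patient", {
  co <- generate_cohort(cohort_config(n_patients = 4, seed = 13))
  for (p in co$patients) {
    vols <- unique(t(vapply(p$conditions, function(cd)
      c(cd$ptv$PTV1$volume, cd$ptv$PTV2$volume), numeric(2))))
    expect_equal(nrow(vols), 1)  # one anatomy per patient
    for (cd in p$conditions) {
      for (tv in names(cd$ptv)) {
        x <- cd$ptv[[tv]]
        rx <- x$prescription
        expect_lt(d_at_volume(x$dvh, 0.1), 1.01 * rx)
        expect_gt(d_at_volume(x$dvh, 98), 0.99 * rx)
        hi <- homogeneity_index(x$dvh)
        expect_gte(hi, 1.02)
        expect_lte(hi, 1.10)
        ci <- conformity_index(x$v95_volume, x$volume)
        expect_gt(ci, 96)
      }
    }
  }
  expect_equal(unname(co$patients[[1]]$conditions$IMRT_conv$ptv$PTV1$prescription), 60)
  expect_equal(unname(co$patients[[1]]$conditions$IMRT_conv$ptv$PTV2$prescription), 52)
  rm(co); gc(FALSE)
})

test_that("overlap outlier: near-prescription vessels, capped sparing, small summary impact", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 23, ptv_bin_width = 0.005))
  ol <- co$patients[[which(vapply(co$patients, `[[`, TRUE, "outlier"))]]
  expect_equal(ol$id, 8L)
  conv <- vessel_mean_dose(ol$conditions$IMPT_conv)
  b80 <- vessel_mean_dose(ol$conditions$IMPT_bvs80)
  b90 <- vessel_mean_dose(ol$conditions$IMPT_bvs90)
  expect_gt(conv, 40)                      # vessels near the prescription scale
  expect_gt(b80 / conv, 0.98)
  expect_gt(b90 / conv, 0.98)
  expect_lt(abs(b80 - conv) / conv, 0.02)  # < 2% change across levels

  # excluding the outlier barely moves the percent-reduction summary:
  # simulate IMPT conv/bvs80 for all patients at small particle counts
  model <- list(male = circulation_model("male"), female = circulation_model("female"))
  dm <- sapply(c("IMPT_conv", "IMPT_bvs80"), function(cn)
    vapply(co$patients, function(p) {
      cd <- p$conditions[[cn]]
      simulate_blood_dose(model[[cd$sex]], cd$organ_dvhs, cd$schedule,
                          n_particles = 1500, seed = 1000 + p$id)$metrics[["Dmean"]]
    }, 0))
  red <- 100 * (dm[, 1] - dm[, 2]) / dm[, 1]
  keep <- !vapply(co$patients, `[[`, TRUE, "outlier")
  expect_lt(abs(median(red) - median(red[keep])), 1)
  # the outlier's own benefit is negligible
  expect_lt(red[!keep], 2)
  rm(co); gc(FALSE)
})

test_that("cohort round-trips through the on-disk layout; corruption is caught by name", {
  co <- generate_cohort(cohort_config(n_patients = 2, seed = 3, male_fraction = 0.5,
                                      ptv_bin_width = 0.01))
  path <- file.path(tempdir(), "cohort_rt")
  on.exit(unlink(path, recursive = TRUE), add = TRUE)
  write_cohort(co, path)
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  expect_equal(manifest$n_conditions, 12)
  expect_equal(manifest$n_patients, 2)

  co2 <- read_cohort(path)
  expect_length(co2$patients, 2)
  expect_identical(vapply(co$patients, `[[`, "", "sex"),
                   vapply(co2$patients, `[[`, "", "sex"))
  a <- co$patients[[2]]$conditions$IMPT_bvs90
  b <- co2$patients[[2]]$conditions$IMPT_bvs90
  expect_identical(a$organ_dvhs$large_veins$volume, b$organ_dvhs$large_veins$volume)
  expect_identical(a$organ_dvhs$large_veins$dose, b$organ_dvhs$large_veins$dose)
  expect_equal(a$ptv$PTV1$volume, b$ptv$PTV1$volume)
  expect_equal(a$schedule$field_beam_on, b$schedule$field_beam_on)

  # corrupt one DVH file: integrity error names patient and condition
  f <- file.path(path, "patient_001", "IMRT_conv", "dvh.csv")
  cat("tamper\n", file = f, append = TRUE)
  expect_error(read_cohort(path), "patient 1.*IMRT_conv|IMRT_conv.*patient 1")
})
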