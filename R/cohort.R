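# Synthetic head-and-neck plan cohort. Plans are emulated at the DVH level:
# the generator enforces the dose-level consequences of inverse planning
# (target-coverage bands met, vessel mean-dose scaling under the sparing
# constraints, the proton low-dose-bath reduction, small localized
# redistribution to brain and away from the esophagus) without modelling the
# optimizer itself.

.vessel_organs <- c("large_arteries", "large_veins")

#' Default organ-class dose priors
#'
#' Lognormal priors for the course-level mean dose (Gy) of each circulation
#' compartment in a conventional photon head-and-neck plan, plus whether the
#' organ belongs to the low-dose bath that proton plans shrink. The numbers
#' are free parameters with defaults chosen (via the identity
#' `E[blood Dmean] = sum_o (V_o/V_tot) * Dmean_o`) so that simulated
#' non-outlier blood mean doses land in the 1-2 Gy range typical of
#' head-and-neck plans; they are inputs, not claims about any specific plan.
#'
#' @return data.frame with columns `organ`, `meanlog`, `sdlog`, `bath`.
#' @export
default_organ_priors <- function() {
  d <- data.frame(
    organ = c("aorta", "large_arteries", "large_veins", "superior_vena_cava",
              "thyroid", "esophagus", "lymph_nodes", "skeletal_muscle",
              "bone", "skin", "brain", "bronchi", "lungs", "stomach",
              "fat", "residual_body"),
    median_gy = c(4.0, 5.0, 3.5, 2.5,
                  25, 12, 8, 2.0,
                  2.0, 1.5, 1.5, 1.0, 0.4, 0.15,
                  0.8, 0.45),
    sdlog = c(0.40, 0.35, 0.35, 0.40,
              0.40, 0.40, 0.50, 0.30,
              0.30, 0.30, 0.50, 0.50, 0.50, 0.50,
              0.40, 0.30),
    bath = c(FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, FALSE, TRUE,
             TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
             TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  d$meanlog <- log(d$median_gy)
  d
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients (default 20; >= 2 when statistics
#'   are wanted downstream).
#' @param male_fraction fraction of male patients (default 15/20); the male
#'   count is `round(n_patients * male_fraction)` and sexes are permuted
#'   across patient ids.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param vessel_scaling named vector of vessel mean-dose scalings per
#'   constraint level relative to the conventional plan.
#' @param impt_low_dose_factor multiplier (< 1) applied to the mean dose of
#'   low-dose-bath organs under proton plans.
#' @param brain_dmax_increase range of the relative brain/brainstem dose
#'   increase under vessel-sparing plans (localized redistribution).
#' @param esophagus_dmean_decrease range of the relative esophagus mean-dose
#'   decrease under vessel-sparing plans (concurrent sparing).
#' @param include_overlap_outlier include one patient whose large vessels
#'   overlap the target (vessel doses near prescription, negligible benefit
#'   from vessel sparing).
#' @param organ_priors see [default_organ_priors()].
#' @param prescriptions named vector of prescription doses, Gy.
#' @param n_fractions fractions per course.
#' @param organ_bin_width dose bin for organ DVHs, Gy.
#' @param ptv_bin_width dose bin for PTV DVHs, Gy (fine, because the
#'   coverage bands constrain quantiles within fractions of a percent of the
#'   prescription).
#' @param organ_rel_spread relative width of the organ sigmoid survival
#'   curves.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20, male_fraction = 15 / 20, seed = NULL,
                          vessel_scaling = c(conv = 1.0, bvs90 = 0.9, bvs80 = 0.8),
                          impt_low_dose_factor = 0.55,
                          brain_dmax_increase = c(0.01, 0.03),
                          esophagus_dmean_decrease = c(0.05, 0.10),
                          include_overlap_outlier = TRUE,
                          organ_priors = default_organ_priors(),
                          prescriptions = c(PTV1 = 60, PTV2 = 52),
                          n_fractions = 33,
                          organ_bin_width = 0.01,
                          ptv_bin_width = 5e-4,
                          organ_rel_spread = 0.35) {
  stopifnot(n_patients >= 1, male_fraction >= 0, male_fraction <= 1)
  if (any(vessel_scaling <= 0) || any(vessel_scaling > 1)) {
    stop("vessel scalings must lie in (0, 1]")
  }
  if (impt_low_dose_factor <= 0 || impt_low_dose_factor > 1) {
    stop("'impt_low_dose_factor' must lie in (0, 1]")
  }
  if (any(brain_dmax_increase < 0) || any(esophagus_dmean_decrease < 0) ||
      any(esophagus_dmean_decrease >= 1)) {
    stop("invalid redistribution effect sizes")
  }
  structure(list(n_patients = as.integer(n_patients), male_fraction = male_fraction,
                 seed = seed, vessel_scaling = vessel_scaling,
                 impt_low_dose_factor = impt_low_dose_factor,
                 brain_dmax_increase = brain_dmax_increase,
                 esophagus_dmean_decrease = esophagus_dmean_decrease,
                 include_overlap_outlier = include_overlap_outlier,
                 organ_priors = organ_priors, prescriptions = prescriptions,
                 n_fractions = as.integer(n_fractions),
                 organ_bin_width = organ_bin_width, ptv_bin_width = ptv_bin_width,
                 organ_rel_spread = organ_rel_spread),
            class = "cohort_config")
}

# normalized sigmoid survival shape and its mean (memoized)
.organ_shape <- local({
  cache <- new.env(parent = emptyenv())
  function(rel_spread) {
    key <- format(rel_spread, digits = 12)
    if (is.null(cache[[key]])) {
      s0 <- function(x) (1 + exp(-1 / rel_spread)) / (1 + exp((x - 1) / rel_spread))
      xs <- seq(0, 1 + rel_spread * 25, by = 1e-4)
      v <- s0(xs)
      mu0 <- sum((v[-1] + v[-length(v)]) / 2) * 1e-4
      cache[[key]] <- list(fn = s0, mean = mu0, xmax = 1 + rel_spread * 25)
    }
    cache[[key]]
  }
})

# sigmoid survival DVH with (trapezoid) mean dose equal to target_mean
.build_organ_dvh <- function(target_mean, rel_spread, bin_width) {
  sh <- .organ_shape(rel_spread)
  alpha <- target_mean / sh$mean
  dvh_from_function(function(d) sh$fn(d / alpha), max_dose = alpha * sh$xmax,
                    bin_width = bin_width)
}

# Piecewise-linear PTV survival anchors (fractions of prescription).
# Engineered so that D98% > 0.99 Rx, D0.1% < 1.01 Rx and HI = D5%/D95%
# falls inside [1.02, 1.10]; jointly these pin HI just above 1.02.
.ptv_anchors <- function(mid_jitter = 0, shoulder_v = 0.075) {
  list(d = c(0, 0.98900, 0.990030, 0.990110, 1.000 + mid_jitter,
             1.009870, 1.009962, 1.009976, 1.009992),
       v = c(1, 1, 0.983, 0.943, 0.50, shoulder_v, 0.030, 0.0015, 0))
}

.build_ptv_dvh <- function(rx, bin_width, mid_jitter, shoulder_v) {
  a <- .ptv_anchors(mid_jitter, shoulder_v)
  dvh_from_function(function(d) stats::approx(a$d * rx, a$v, xout = d, rule = 2)$y,
                    max_dose = max(a$d) * rx, bin_width = bin_width)
}

#' Generate a synthetic plan cohort
#'
#' Produces `n_patients` synthetic patients, each with six plan conditions
#' (IMRT/IMPT crossed with conventional, BVS-90% and BVS-80% vessel-sparing
#' levels). Per patient, baseline organ mean doses are drawn from
#' organ-class lognormal priors and turned into sigmoid survival DVHs;
#' proton plans shrink low-dose-bath organ doses by
#' `impt_low_dose_factor`; vessel-sparing levels scale the large-vessel DVH
#' dose axes so the vessel mean-dose ratio to the conventional plan equals
#' the configured scaling exactly, and apply small redistribution effects
#' (brain dose up 1-3%, esophagus mean dose down 5-10%). PTV DVHs satisfy
#' the coverage bands `D0.1% < 1.01 Rx` and `D98% > 0.99 Rx`. When enabled,
#' the last patient is a vessel-target-overlap outlier: vessel mean doses
#' near the prescription and vessel scaling capped at 0.995/0.99 so sparing
#' changes vessel dose by under 2%.
#'
#' @param config a [cohort_config()].
#' @return an object of class `plan_cohort`: a list with `config` and
#'   `patients`; each patient holds `id`, `sex`, `outlier` and a named list
#'   `conditions` (`IMRT_conv`, ..., `IMPT_bvs80`) of `plan_condition`
#'   objects carrying the organ DVH map, PTV DVHs and volumes, 95%-isodose
#'   volumes and the beam schedule.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_patients
  n_male <- round(np * config$male_fraction)
  sexes <- sample(c(rep("male", n_male), rep("female", np - n_male)))
  outlier_id <- if (config$include_overlap_outlier) np else NA_integer_
  priors <- config$organ_priors
  levels <- c("conv", "bvs90", "bvs80")
  rs <- config$organ_rel_spread

  patients <- vector("list", np)
  for (p in seq_len(np)) {
    is_outlier <- identical(p, as.integer(outlier_id))
    base <- stats::rlnorm(nrow(priors), priors$meanlog, priors$sdlog)
    names(base) <- priors$organ
    if (is_outlier) {
      # vessels overlap the target: vessel doses near the prescription scale
      base["large_arteries"] <- 55 * exp(stats::rnorm(1, 0, 0.03))
      base["large_veins"] <- 52 * exp(stats::rnorm(1, 0, 0.03))
      base["aorta"] <- 20 * exp(stats::rnorm(1, 0, 0.05))
      base["superior_vena_cava"] <- 15 * exp(stats::rnorm(1, 0, 0.05))
    }
    # one anatomy per patient: PTV volumes shared by all six plans
    ptv_vol <- stats::setNames(
      vapply(names(config$prescriptions), function(tv)
        stats::rlnorm(1, log(if (tv == "PTV1") 220 else 450), 0.3), 0),
      names(config$prescriptions))
    base_dvhs <- stats::setNames(
      lapply(base, .build_organ_dvh, rel_spread = rs,
             bin_width = config$organ_bin_width),
      names(base))
    conditions <- list()
    for (modality in c("IMRT", "IMPT")) {
      conv_dvhs <- base_dvhs
      if (modality == "IMPT") {
        # low-dose bath shrinks by an exact dose-axis scaling
        for (o in priors$organ[priors$bath]) {
          conv_dvhs[[o]] <- scale_dose(base_dvhs[[o]], config$impt_low_dose_factor)
        }
      }
      sched <- beam_schedule(modality, n_fractions = config$n_fractions)
      # per-plan conformity: a patient/modality baseline that degrades
      # slightly (but stays above 96%) as vessel constraints tighten
      ci_base <- stats::setNames(
        vapply(names(config$prescriptions), function(tv) stats::runif(1, 97.2, 99.4), 0),
        names(config$prescriptions))
      for (level in levels) {
        organ_dvhs <- conv_dvhs
        if (level != "conv") {
          f <- if (is_outlier) {
            if (level == "bvs90") 0.995 else 0.99
          } else {
            unname(config$vessel_scaling[[level]])
          }
          for (o in .vessel_organs) organ_dvhs[[o]] <- scale_dose(conv_dvhs[[o]], f)
          bi <- stats::runif(1, config$brain_dmax_increase[1], config$brain_dmax_increase[2])
          ed <- stats::runif(1, config$esophagus_dmean_decrease[1],
                             config$esophagus_dmean_decrease[2])
          organ_dvhs[["brain"]] <- scale_dose(conv_dvhs[["brain"]], 1 + bi)
          organ_dvhs[["esophagus"]] <- scale_dose(conv_dvhs[["esophagus"]], 1 - ed)
        }
        ptv <- list()
        for (tv in names(config$prescriptions)) {
          rx <- config$prescriptions[[tv]]
          mid_j <- stats::runif(1, -0.002, 0.002)
          sh_v <- stats::runif(1, 0.070, 0.085)
          vol <- ptv_vol[[tv]]
          ci <- ci_base[[tv]] -
            switch(level, conv = 0, bvs90 = stats::runif(1, 0.05, 0.4),
                   bvs80 = stats::runif(1, 0.3, 0.8))
          ci <- max(ci, 96.2)
          ptv[[tv]] <- list(dvh = .build_ptv_dvh(rx, config$ptv_bin_width, mid_j, sh_v),
                            prescription = rx,
                            volume = vol,
                            v95_volume = vol * ci / 100)
        }
        conditions[[paste(modality, level, sep = "_")]] <-
          structure(list(patient_id = p, sex = sexes[p], modality = modality,
                         level = level, organ_dvhs = organ_dvhs, ptv = ptv,
                         schedule = sched),
                    class = "plan_condition")
      }
    }
    patients[[p]] <- list(id = p, sex = sexes[p], outlier = is_outlier,
                          conditions = conditions)
  }
  structure(list(config = config, patients = patients), class = "plan_cohort")
}

#' @export
print.plan_cohort <- function(x, ...) {
  np <- length(x$patients)
  sexes <- vapply(x$patients, `[[`, "", "sex")
  cat(sprintf("Synthetic plan cohort: %d patients (%d male / %d female), %d plan conditions\n",
              np, sum(sexes == "male"), sum(sexes == "female"),
              sum(vapply(x$patients, function(p) length(p$conditions), 0L))))
  if (any(vapply(x$patients, `[[`, TRUE, "outlier"))) {
    cat(sprintf("  includes vessel-overlap outlier: patient %d\n",
                which(vapply(x$patients, `[[`, TRUE, "outlier"))))
  }
  invisible(x)
}

#' @export
print.plan_condition <- function(x, ...) {
  cat(sprintf("Plan condition: patient %d (%s), %s / %s, %d organ DVHs\n",
              x$patient_id, x$sex, x$modality, x$level, length(x$organ_dvhs)))
  invisible(x)
}

#' Vessel mean dose of a plan condition
#'
#' Volume-weighted mean dose over the large arteries and large veins, the
#' quantity constrained by the vessel-sparing levels. Weights come from the
#' circulation model's compartment blood volumes.
#'
#' @param condition a `plan_condition`.
#' @param model optional `circulation_model` for the weights (defaults to
#'   the condition's sex-specific reference model).
#' @return mean dose in Gy.
#' @export
vessel_mean_dose <- function(condition, model = NULL) {
  stopifnot(inherits(condition, "plan_condition"))
  if (is.null(model)) model <- circulation_model(condition$sex)
  w <- model$compartments$blood_volume[match(.vessel_organs, model$compartments$name)]
  m <- vapply(condition$organ_dvhs[.vessel_organs], mean_dose, 0)
  sum(w * m) / sum(w)
}

# ---- cohort serialization -------------------------------------------------

#' Write or read a cohort as a directory of CSVs plus a manifest
#'
#' Layout: `path/<patient>/<modality>_<level>/dvh.csv` (organ DVHs) and
#' `ptv.csv` (PTV DVHs), with `manifest.json` at the top level recording the
#' configuration, patient attributes, schedules, volumes and an MD5 checksum
#' per file. `read_cohort` verifies the checksums and fails with an
#' integrity error naming the patient/condition on any mismatch.
#'
#' @param cohort a `plan_cohort`.
#' @param path directory to create/read.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `plan_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "plan_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (pat in cohort$patients) {
    for (cname in names(pat$conditions)) {
      cond <- pat$conditions[[cname]]
      d <- file.path(path, sprintf("patient_%03d", pat$id), cname)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_dvh_csv(cond$organ_dvhs, file.path(d, "dvh.csv"))
      write_dvh_csv(stats::setNames(lapply(cond$ptv, `[[`, "dvh"), names(cond$ptv)),
                    file.path(d, "ptv.csv"))
      entries[[length(entries) + 1L]] <- list(
        patient_id = pat$id, sex = pat$sex, outlier = pat$outlier,
        condition = cname, modality = cond$modality, level = cond$level,
        dir = file.path(sprintf("patient_%03d", pat$id), cname),
        md5_dvh = unname(tools::md5sum(file.path(d, "dvh.csv"))),
        md5_ptv = unname(tools::md5sum(file.path(d, "ptv.csv"))),
        schedule = unclass(cond$schedule),
        ptv_meta = lapply(cond$ptv, function(t)
          list(prescription = t$prescription, volume = t$volume,
               v95_volume = t$v95_volume))
      )
    }
  }
  manifest <- list(package_version = as.character(utils::packageVersion("circdose")),
                   n_patients = length(cohort$patients),
                   n_conditions = length(entries),
                   config = unclass(cohort$config),
                   conditions = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  cfgl <- manifest$config
  cfgl$organ_priors <- as.data.frame(lapply(cfgl$organ_priors, unlist),
                                     stringsAsFactors = FALSE)
  cfg <- do.call(cohort_config, c(
    cfgl[c("n_patients", "male_fraction", "impt_low_dose_factor",
           "include_overlap_outlier", "n_fractions", "organ_bin_width",
           "ptv_bin_width", "organ_rel_spread")],
    list(seed = if (is.null(cfgl$seed)) NULL else cfgl$seed,
         vessel_scaling = unlist(cfgl$vessel_scaling),
         brain_dmax_increase = unlist(cfgl$brain_dmax_increase),
         esophagus_dmean_decrease = unlist(cfgl$esophagus_dmean_decrease),
         organ_priors = cfgl$organ_priors,
         prescriptions = unlist(cfgl$prescriptions))))
  patients <- list()
  for (e in manifest$conditions) {
    d <- file.path(path, e$dir)
    for (fl in c("dvh.csv", "ptv.csv")) {
      f <- file.path(d, fl)
      if (!file.exists(f)) {
        stop(sprintf("integrity error: patient %d condition %s: missing %s",
                     e$patient_id, e$condition, fl))
      }
    }
    if (!identical(unname(tools::md5sum(file.path(d, "dvh.csv"))), e$md5_dvh) ||
        !identical(unname(tools::md5sum(file.path(d, "ptv.csv"))), e$md5_ptv)) {
      stop(sprintf("integrity error: patient %d condition %s: checksum mismatch",
                   e$patient_id, e$condition))
    }
    organ_dvhs <- read_dvh_csv(file.path(d, "dvh.csv"))
    ptv_dvhs <- read_dvh_csv(file.path(d, "ptv.csv"))
    ptv <- lapply(names(e$ptv_meta), function(tv)
      list(dvh = ptv_dvhs[[tv]],
           prescription = e$ptv_meta[[tv]]$prescription,
           volume = e$ptv_meta[[tv]]$volume,
           v95_volume = e$ptv_meta[[tv]]$v95_volume))
    names(ptv) <- names(e$ptv_meta)
    sch <- e$schedule
    sched <- beam_schedule(sch$modality, sch$n_fields, sch$field_beam_on,
                           sch$inter_field_gap, sch$n_fractions)
    pid <- as.integer(e$patient_id)
    key <- as.character(pid)
    if (is.null(patients[[key]])) {
      patients[[key]] <- list(id = pid, sex = e$sex, outlier = isTRUE(e$outlier),
                              conditions = list())
    }
    patients[[key]]$conditions[[e$condition]] <-
      structure(list(patient_id = pid, sex = e$sex, modality = e$modality,
                     level = e$level, organ_dvhs = organ_dvhs, ptv = ptv,
                     schedule = sched),
                class = "plan_condition")
  }
  if (length(patients) != manifest$n_patients) {
    stop("integrity error: manifest patient count does not match directory contents")
  }
  patients <- patients[order(as.integer(names(patients)))]
  names(patients) <- NULL
  structure(list(config = cfg, patients = patients), class = "plan_cohort")
}
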