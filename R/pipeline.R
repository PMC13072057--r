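# End-to-end study pipeline: cohort -> per-plan blood-dose simulation ->
# plan-quality and blood metrics -> paired statistics -> report tables and
# reproducibility manifest.

.blood_metric_names <- c("Dmean", "D90", "D70", "D50", "D30", "D10", "D2", "V0.9Gy")
.level_labels <- c(conv = "Conv", bvs90 = "BVS-90%", bvs80 = "BVS-80%")

#' Study configuration
#'
#' @param n_patients synthetic cohort size.
#' @param seed master seed for the whole run (cohort generation and every
#'   simulation draw from one stream).
#' @param n_particles blood particles per plan simulation.
#' @param residence,fraction_mode,bin_width passed to
#'   [simulate_blood_dose()].
#' @param always_posthoc run post-hoc pairwise tests even when the Friedman
#'   test is not significant.
#' @param modality_test also run a paired Wilcoxon for the IMRT-vs-IMPT
#'   contrast at each constraint level (the primary modality comparison is
#'   descriptive).
#' @param cohort a [cohort_config()]; its `seed` is ignored in favour of the
#'   master seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_patients = 20, seed = 1, n_particles = 1e4,
                         residence = "fixed", fraction_mode = "resample",
                         bin_width = 0.01, always_posthoc = FALSE,
                         modality_test = TRUE,
                         cohort = cohort_config(n_patients = n_patients)) {
  cohort$seed <- NULL   # the master seed governs the single RNG stream
  cohort$n_patients <- as.integer(n_patients)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 n_particles = as.integer(n_particles), residence = residence,
                 fraction_mode = fraction_mode, bin_width = bin_width,
                 always_posthoc = always_posthoc, modality_test = modality_test,
                 cohort = cohort),
            class = "study_config")
}

#' Run the full circulating-blood dose study
#'
#' Generates (or accepts) a plan cohort, simulates the circulating-blood
#' dose for every plan condition, computes plan-quality indices and blood
#' DVH metrics, runs the paired statistics, and optionally writes the
#' report bundle (CSV tables, markdown report and a JSON manifest) to
#' `out_dir`. The whole run is driven by `config$seed`; re-running with the
#' same configuration reproduces every numeric output bit-identically.
#'
#' @param config a [study_config()].
#' @param cohort optional pre-built `plan_cohort` (or a path to one written
#'   by [write_cohort()]); when supplied, the cohort stage is skipped.
#' @param out_dir output directory, or NULL to skip writing.
#' @return an object of class `blood_study` with elements `config`,
#'   `cohort`, `blood_metrics` (long data.frame), `plan_quality`,
#'   `blood_stats`, `plan_quality_stats`, `reductions`,
#'   `modality_contrast`, `tables` (see [report_tables()]) and `manifest`.
#' @export
run_study <- function(config = study_config(), cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  set.seed(config$seed)
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "plan_cohort"))

  models <- list(male = circulation_model("male"),
                 female = circulation_model("female"))

  bm <- list()
  pq <- list()
  for (pat in cohort$patients) {
    for (cname in names(pat$conditions)) {
      cond <- pat$conditions[[cname]]
      sim <- simulate_blood_dose(models[[cond$sex]], cond$organ_dvhs,
                                 cond$schedule, n_particles = config$n_particles,
                                 residence = config$residence,
                                 fraction_mode = config$fraction_mode,
                                 bin_width = config$bin_width)
      bm[[length(bm) + 1L]] <- data.frame(
        patient = pat$id, sex = pat$sex, outlier = pat$outlier,
        modality = cond$modality, level = cond$level,
        metric = names(sim$metrics), value = unname(sim$metrics))
      for (tv in names(cond$ptv)) {
        pq[[length(pq) + 1L]] <- data.frame(
          patient = pat$id, modality = cond$modality, level = cond$level,
          target = tv,
          hi = homogeneity_index(cond$ptv[[tv]]$dvh),
          ci = conformity_index(cond$ptv[[tv]]$v95_volume, cond$ptv[[tv]]$volume))
      }
    }
  }
  blood_metrics <- do.call(rbind, bm)
  plan_quality <- do.call(rbind, pq)

  lv <- names(.level_labels)
  wide <- function(df, val) {  # patients x levels matrix for one metric
    m <- sapply(lv, function(l) df$value[df$level == l][order(df$patient[df$level == l])])
    rownames(m) <- sort(unique(df$patient))
    colnames(m) <- .level_labels[lv]
    m
  }

  blood_stats <- list()
  reductions <- list()
  for (mod in c("IMRT", "IMPT")) {
    for (met in .blood_metric_names) {
      df <- blood_metrics[blood_metrics$modality == mod & blood_metrics$metric == met, ]
      m <- wide(df)
      cl <- compare_levels(m, always_posthoc = config$always_posthoc)
      blood_stats[[paste(mod, met, sep = ".")]] <-
        list(modality = mod, metric = met, friedman = cl$friedman, posthoc = cl$posthoc)
      rs <- reduction_summary(m, baseline = "Conv")
      rs$modality <- mod
      rs$metric <- met
      reductions[[paste(mod, met, sep = ".")]] <- rs
    }
  }
  reductions <- do.call(rbind, c(reductions, make.row.names = FALSE))

  plan_quality_stats <- list()
  for (mod in c("IMRT", "IMPT")) {
    for (tv in unique(plan_quality$target)) {
      for (ix in c("hi", "ci")) {
        df <- plan_quality[plan_quality$modality == mod & plan_quality$target == tv, ]
        m <- sapply(lv, function(l) df[[ix]][df$level == l][order(df$patient[df$level == l])])
        colnames(m) <- .level_labels[lv]
        cl <- compare_levels(m, always_posthoc = config$always_posthoc)
        plan_quality_stats[[paste(mod, tv, toupper(ix), sep = ".")]] <-
          list(modality = mod, target = tv, index = toupper(ix),
               values = m, friedman = cl$friedman, posthoc = cl$posthoc)
      }
    }
  }

  modality_contrast <- list()
  for (l in lv) {
    for (met in .blood_metric_names) {
      a <- blood_metrics[blood_metrics$modality == "IMRT" &
                           blood_metrics$level == l & blood_metrics$metric == met, ]
      b <- blood_metrics[blood_metrics$modality == "IMPT" &
                           blood_metrics$level == l & blood_metrics$metric == met, ]
      a <- a[order(a$patient), ]
      b <- b[order(b$patient), ]
      ok <- a$value != 0
      row <- data.frame(level = .level_labels[[l]], metric = met,
                        imrt_median = stats::median(a$value),
                        impt_median = stats::median(b$value),
                        mean_pct_reduction = mean(100 * (a$value[ok] - b$value[ok]) / a$value[ok]),
                        p_wilcoxon = if (config$modality_test)
                          wilcoxon_signed_rank(a$value, b$value)$p.value else NA_real_)
      modality_contrast[[paste(l, met, sep = ".")]] <- row
    }
  }
  modality_contrast <- do.call(rbind, c(modality_contrast, make.row.names = FALSE))

  res <- structure(list(config = config, cohort = cohort,
                        blood_metrics = blood_metrics, plan_quality = plan_quality,
                        blood_stats = blood_stats,
                        plan_quality_stats = plan_quality_stats,
                        reductions = reductions,
                        modality_contrast = modality_contrast),
                   class = "blood_study")
  res$tables <- report_tables(res)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(blood_metrics = "blood_metrics.csv", plan_quality = "plan_quality.csv",
               reductions = "reductions.csv", modality_contrast = "modality_contrast.csv")
    for (nm in names(files)) {
      data.table::fwrite(res[[nm]], file.path(out_dir, files[[nm]]))
    }
    data.table::fwrite(res$tables$plan_quality, file.path(out_dir, "table_plan_quality.csv"))
    data.table::fwrite(res$tables$blood, file.path(out_dir, "table_blood_metrics.csv"))
    data.table::fwrite(res$tables$reductions, file.path(out_dir, "table_reductions.csv"))
    writeLines(res$tables$markdown, file.path(out_dir, "report.md"))
    written <- file.path(out_dir, c(unname(files), "table_plan_quality.csv",
                                    "table_blood_metrics.csv", "table_reductions.csv",
                                    "report.md"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("circdose")),
      seed = config$seed,
      n_particles = config$n_particles,
      n_patients = length(cohort$patients),
      n_conditions = sum(vapply(cohort$patients, function(p) length(p$conditions), 0L)),
      residence = config$residence, fraction_mode = config$fraction_mode,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = lapply(stats::setNames(written, basename(written)),
                       function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}

.fmt_mr <- function(v, digits = 3) {
  sprintf("%.*f (%.*f-%.*f)", digits, stats::median(v), digits, min(v), digits, max(v))
}

.md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Build the study report tables
#'
#' Produces (i) the target-coverage table (HI and CI as median (range) per
#' condition with Friedman and Bonferroni-corrected post-hoc p-values),
#' (ii) the circulating-blood metric table (Dmean, D90%...D2%, V0.9Gy as
#' median (range) per condition), and (iii) the reduction-summary table,
#' plus a markdown rendering of all three.
#'
#' @param results a `blood_study` object from [run_study()].
#' @return a list with data.frames `plan_quality`, `blood`, `reductions`
#'   and a character vector `markdown`.
#' @export
report_tables <- function(results) {
  stopifnot(inherits(results, "blood_study"))
  lv <- .level_labels

  pq_rows <- lapply(results$plan_quality_stats, function(s) {
    vals <- s$values
    ph <- s$posthoc
    fmt_d <- if (s$index == "HI") 3 else 1
    row <- data.frame(modality = s$modality, target = s$target, index = s$index)
    for (l in colnames(vals)) row[[l]] <- .fmt_mr(vals[, l], fmt_d)
    row$friedman_p <- signif(s$friedman$p.value, 3)
    for (j in seq_len(3)) {
      row[[paste0("p_", gsub(" ", "", c("Conv vs BVS-90%", "Conv vs BVS-80%",
                                        "BVS-90% vs BVS-80%")[j]))]] <-
        if (is.null(ph)) NA_real_ else signif(ph$p_adj[j], 3)
    }
    row
  })
  pq_tab <- do.call(rbind, c(pq_rows, make.row.names = FALSE))

  bm <- results$blood_metrics
  bl_rows <- list()
  for (mod in c("IMRT", "IMPT")) {
    for (met in .blood_metric_names) {
      row <- data.frame(modality = mod, metric = met)
      for (l in names(lv)) {
        v <- bm$value[bm$modality == mod & bm$level == l & bm$metric == met]
        row[[lv[[l]]]] <- .fmt_mr(v, if (met == "V0.9Gy") 1 else 3)
      }
      s <- results$blood_stats[[paste(mod, met, sep = ".")]]
      row$friedman_p <- signif(s$friedman$p.value, 3)
      bl_rows[[paste(mod, met)]] <- row
    }
  }
  bl_tab <- do.call(rbind, c(bl_rows, make.row.names = FALSE))

  red <- results$reductions
  red_tab <- red[red$condition != "Conv",
                 c("modality", "metric", "condition", "median", "min", "max",
                   "mean_pct_reduction", "n")]

  md <- c("# Circulating-blood dose study report", "",
          "## Target coverage (HI / CI)", "", .md_table(pq_tab), "",
          "## Circulating-blood DVH metrics (median (range))", "", .md_table(bl_tab), "",
          "## Per-patient reductions vs conventional plan", "",
          .md_table(within(red_tab, mean_pct_reduction <- round(mean_pct_reduction, 2))))
  list(plan_quality = pq_tab, blood = bl_tab, reductions = red_tab, markdown = md)
}

#' @export
print.blood_study <- function(x, ...) {
  bm <- x$blood_metrics
  cat(sprintf("Blood-dose study: %d patients x 6 conditions, %d particles/plan (seed %d)\n",
              length(x$cohort$patients), x$config$n_particles, x$config$seed))
  for (mod in c("IMRT", "IMPT")) {
    v <- bm$value[bm$modality == mod & bm$level == "conv" & bm$metric == "Dmean"]
    cat(sprintf("  %s-Conv blood Dmean: median %.3f Gy (range %.3f-%.3f)\n",
                mod, stats::median(v), min(v), max(v)))
  }
  r <- x$reductions
  for (mod in c("IMRT", "IMPT")) {
    rr <- r[r$modality == mod & r$metric == "Dmean" & r$condition == "BVS-80%", ]
    cat(sprintf("  %s BVS-80%% mean per-patient Dmean reduction: %.1f%%\n",
                mod, rr$mean_pct_reduction))
  }
  invisible(x)
}
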