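# End-to-end analysis: exclusion, per-subject measures, group
# comparisons, ANOVAs, correlations, and a serialisable results bundle.

#' Default analysis configuration
#'
#' All design constants default to the study values: 6 confidence
#' levels, 180 perceptual trials, 100 learning / 200 recognition trials,
#' staircase step 0.03 from a 0.20 distractor baseline, alpha 0.05,
#' accuracy exclusion at mean - 8 SD, negative M-ratio subjects retained.
#'
#' @param ... named overrides of the defaults.
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    K = 6L,
    pad_scheme = "if-needed",
    n_sd_exclusion = 8,
    baseline_contrast = 0.20,
    retain_negative_m_ratio = TRUE,
    n_perc_trials = 180L,
    n_learn = 100L,
    n_test = 200L,
    staircase_step = 0.03,
    staircase_start_delta = 0.20)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a configuration file
#'
#' Declarative YAML; round-trips losslessly.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_config` returns a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Internal: stable checksum of a config (via its YAML serialisation).
config_checksum <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full group analysis on a trial dataset
#'
#' Applies the accuracy exclusion rule (perceptual accuracy below the
#' whole-sample mean minus 8 SD), extracts per-subject measures, and runs
#' the group statistics: Levene-guided t-tests on every Table-style
#' measure, mixed Group x Task ANOVAs on mean confidence and on
#' metacognition (twice: mixed units, i.e. equal-variance perceptual with
#' unequal-variance memory M-ratio, and all-equal-variance), the
#' Group x Imageability ANOVA on memory metacognition, and the Pearson
#' correlations (M-ratio vs sensitivity per task; cross-task
#' metacognition pooled and per group; high vs low imageability per
#' group). No multiple-testing correction is applied.
#'
#' @param trials trial data frame (package CSV schema).
#' @param config a `run_config`.
#' @return object of class `results_bundle`: `measures`, `excluded`,
#'   `comparisons` (named list of `group_comparison`), `anovas`,
#'   `correlations`, `provenance`.
#' @export
analyze_trials <- function(trials, config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  # exclusion on perceptual accuracy
  perc <- trials[trials$task == "perceptual", , drop = FALSE]
  excluded <- character(0)
  if (nrow(perc) > 0) {
    acc <- tapply(perc$correct, perc$subject_id, mean)
    if (length(acc) >= 2) {
      excluded <- names(acc)[exclusion_filter(as.numeric(acc),
                                              config$n_sd_exclusion)]
      trials <- trials[!(trials$subject_id %in% excluded), , drop = FALSE]
    }
  }

  measures <- extract_measures(trials, K = config$K,
                               pad_scheme = config$pad_scheme,
                               baseline_contrast = config$baseline_contrast)
  if (!config$retain_negative_m_ratio) {
    for (cl in c("perc_m_ratio", "mem_m_ratio_uv", "mem_m_ratio_ev",
                 "mem_m_ratio_high", "mem_m_ratio_low")) {
      measures[[cl]][measures[[cl]] < 0] <- NA_real_
    }
  }

  cmp_measures <- c("perc_threshold", "perc_accuracy", "perc_d_prime",
                    "perc_mean_conf", "perc_m_ratio", "perc_mean_rt",
                    "perc_mean_ct", "mem_da", "mem_d_prime", "mem_mean_conf",
                    "mem_m_ratio_uv", "mem_m_ratio_ev", "mem_mean_rt",
                    "mem_mean_ct")
  comparisons <- list()
  for (m in cmp_measures) {
    comparisons[[m]] <- tryCatch(
      compare_groups(measures, m, alpha = config$alpha),
      error = function(e) NULL)
  }

  long2 <- function(pcol, mcol) {
    rbind(data.frame(subject_id = measures$subject_id,
                     group = measures$group, task = "perceptual",
                     value = measures[[pcol]]),
          data.frame(subject_id = measures$subject_id,
                     group = measures$group, task = "memory",
                     value = measures[[mcol]]))
  }
  anovas <- list(
    mean_confidence = tryCatch(
      mixed_anova(long2("perc_mean_conf", "mem_mean_conf")),
      error = function(e) NULL),
    metacognition_mixed_units = tryCatch(
      mixed_anova(long2("perc_m_ratio", "mem_m_ratio_uv")),
      error = function(e) NULL),
    metacognition_equal_variance = tryCatch(
      mixed_anova(long2("perc_m_ratio", "mem_m_ratio_ev")),
      error = function(e) NULL),
    imageability = tryCatch(
      mixed_anova(rbind(
        data.frame(subject_id = measures$subject_id, group = measures$group,
                   imageability = "high", value = measures$mem_m_ratio_high),
        data.frame(subject_id = measures$subject_id, group = measures$group,
                   imageability = "low", value = measures$mem_m_ratio_low)),
        within = "imageability"),
      error = function(e) NULL))

  cor_safe <- function(x, y) {
    tryCatch(pearson_cor(x, y), error = function(e) NULL)
  }
  by_group <- split(measures, measures$group)
  correlations <- list(
    perc_m_ratio_vs_d_prime = cor_safe(measures$perc_m_ratio,
                                       measures$perc_d_prime),
    mem_m_ratio_vs_da = cor_safe(measures$mem_m_ratio_uv, measures$mem_da),
    cross_task_pooled = cor_safe(measures$perc_m_ratio,
                                 measures$mem_m_ratio_uv))
  for (g in names(by_group)) {
    correlations[[paste0("cross_task_", g)]] <-
      cor_safe(by_group[[g]]$perc_m_ratio, by_group[[g]]$mem_m_ratio_uv)
    correlations[[paste0("imageability_high_vs_low_", g)]] <-
      cor_safe(by_group[[g]]$mem_m_ratio_high, by_group[[g]]$mem_m_ratio_low)
  }

  structure(list(
    measures = measures,
    excluded = excluded,
    comparisons = comparisons,
    anovas = anovas,
    correlations = correlations,
    provenance = list(
      package_version = as.character(utils::packageVersion("metacogsdt")),
      config = unclass(config),
      config_checksum = config_checksum(config),
      n_subjects = nrow(measures),
      n_excluded = length(excluded))),
    class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Results bundle:", x$provenance$n_subjects, "subjects",
      if (length(x$excluded)) paste0("(", length(x$excluded), " excluded)"),
      "\n")
  for (m in c("perc_d_prime", "perc_m_ratio", "mem_da", "mem_m_ratio_uv")) {
    cmp <- x$comparisons[[m]]
    if (!is.null(cmp)) {
      cat(sprintf("  %-15s t(%.1f) = %6.2f, p = %.3f (%s)\n", m, cmp$df,
                  cmp$t_statistic, cmp$p_value, cmp$variance_assumption))
    }
  }
  invisible(x)
}

#' Write a results bundle to JSON
#'
#' @param bundle a `results_bundle`.
#' @param path output path.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "results_bundle"))
  jsonlite::write_json(strip_classes(bundle), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# Internal: drop S3 classes so jsonlite serialises plain structures.
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}

#' Plain-text report tables
#'
#' Two aligned tables in the style of a behavioral-measures table (means
#' and SDs of thresholds, accuracy, sensitivity, confidence and M-ratios
#' per group) and a timing table (mean RT and confidence time), formatted
#' mean (SD) to two decimals.
#'
#' @param bundle a `results_bundle`.
#' @return character vector of report lines (also printed invisibly
#'   usable via `cat(report_tables(b), sep = "\n")`).
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  ms <- bundle$measures
  groups <- c("sdi", "control")
  fmt <- function(col, g) {
    v <- ms[[col]][ms$group == g]
    v <- v[is.finite(v)]
    if (!length(v)) return("--")
    sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  }
  line <- function(label, col) {
    sprintf("  %-28s %-16s %-16s", label, fmt(col, "sdi"), fmt(col, "control"))
  }
  out <- c(
    "Behavioral measures: mean (SD)",
    sprintf("  %-28s %-16s %-16s", "", "SDI", "Control"),
    "  Perceptual",
    line("Contrast threshold", "perc_threshold"),
    line("Accuracy", "perc_accuracy"),
    line("d'", "perc_d_prime"),
    line("Mean confidence", "perc_mean_conf"),
    line("M-ratio", "perc_m_ratio"),
    "  Memory",
    line("d' (da)", "mem_da"),
    line("Mean confidence", "mem_mean_conf"),
    line("Unequal-variance M-ratio", "mem_m_ratio_uv"),
    line("Equal-variance M-ratio", "mem_m_ratio_ev"),
    "",
    "Response and confidence times (ms): mean (SD)",
    sprintf("  %-28s %-16s %-16s", "", "SDI", "Control"),
    "  Perceptual",
    line("Mean RT", "perc_mean_rt"),
    line("Mean CT", "perc_mean_ct"),
    "  Memory",
    line("Mean RT", "mem_mean_rt"),
    line("Mean CT", "mem_mean_ct"))
  out
}
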