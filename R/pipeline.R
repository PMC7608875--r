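# End-to-end orchestration: data -> wealth/SES indices -> outcome ->
# per-country inequality -> meta-analysis -> decomposition -> report.

#' Declarative configuration of a full study run
#'
#' @param input Either a [sim_config()] (synthetic study) or a list
#'   `list(csv = path, variable_map = c(new = old, ...))` naming a
#'   child-level CSV and an optional rename map onto the package's
#'   column dictionary (`country`, `cluster`, `weight`, `wealth`,
#'   `severe_wasting` or `whz`, covariates).
#' @param outcome_mode `"flag"` (a 0/1 `severe_wasting` column is
#'   present), `"whz"` (a `whz` z-score column is flagged via
#'   [flag_severe_wasting()]), or `"lms"` (z-scores are computed from
#'   `weight_kg`, `height_cm`, `sex` with the reference at `lms_path`).
#' @param covariates Covariate columns for the decomposition.
#' @param lms_path Path to an LMS reference CSV (for `outcome_mode =
#'   "lms"`).
#' @param link,reference,scheme,normalization Decomposition options, see
#'   [oaxaca_decompose()].
#' @param bootstrap_replicates Cluster-bootstrap replicates for
#'   decomposition uncertainty; 0 skips the bootstrap.
#' @param conf Confidence level for all intervals.
#' @param variance Risk-difference variance mode, see [rd_inference()].
#' @param quadrant_threshold High/low prevalence cut for
#'   [classify_quadrant()]; default the median country prevalence.
#' @param per_country_decomposition Also decompose each country
#'   separately (countries failing preconditions are skipped with a
#'   logged reason).
#' @param output_dir Directory for CSV tables, figures, the JSON results
#'   bundle and the run log; NULL returns results only.
#' @param seed Integer seed governing every stochastic step.
#' @return Object of class `study_config`.
#' @export
study_config <- function(input = sim_config(),
                         outcome_mode = c("flag", "whz", "lms"),
                         covariates = names(default_covariates()),
                         lms_path = NULL,
                         link = "logit", reference = "B",
                         scheme = "population",
                         normalization = "deviation",
                         bootstrap_replicates = 0,
                         conf = 0.95, variance = "cluster",
                         quadrant_threshold = NULL,
                         per_country_decomposition = FALSE,
                         output_dir = NULL, seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  if (!length(covariates))
    stop("covariate list must be non-empty", call. = FALSE)
  cfg <- list(input = input, outcome_mode = outcome_mode,
              covariates = covariates, lms_path = lms_path,
              link = link, reference = reference, scheme = scheme,
              normalization = normalization,
              bootstrap_replicates = bootstrap_replicates,
              conf = conf, variance = variance,
              quadrant_threshold = quadrant_threshold,
              per_country_decomposition = per_country_decomposition,
              output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' @noRd
load_study_data <- function(config, log) {
  if (inherits(config$input, "sim_config")) {
    log("generating synthetic population")
    return(generate_population(config$input))
  }
  path <- config$input$csv
  if (is.null(path)) stop("input must be a sim_config or list(csv = ...)",
                          call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vm <- config$input$variable_map
  if (!is.null(vm)) {
    missing <- setdiff(unname(vm), names(d))
    if (length(missing))
      stop("variable map refers to absent column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    names(d)[match(unname(vm), names(d))] <- names(vm)
  }
  d
}

#' Run a full inequality-and-decomposition study
#'
#' Executes all stages on synthetic or user data: outcome construction,
#' per-country weighted prevalences and risk differences with
#' cluster-robust confidence intervals, odds-ratio homogeneity tests,
#' DerSimonian-Laird pooling, quadrant classification, pooled covariate
#' summary, and the Blinder-Oaxaca decomposition of the poor/non-poor
#' gap (pooled, and per country on request). Countries failing a
#' stage's preconditions are skipped with a logged reason. Re-running
#' with the same configuration (and seed) reproduces the results bundle
#' exactly.
#'
#' @param config A [study_config()].
#' @return List of class `study_report`: `table1`, `table2`, `meta`,
#'   `quadrants`, `decomposition` (and `decomposition_by_country`),
#'   `bootstrap` (if requested), `records_used`, `log`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  log_lines <- character(0)
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))

  d <- load_study_data(config, log)
  check_columns(d, c("country", "cluster", "weight"))

  # outcome
  if (config$outcome_mode == "lms") {
    check_columns(d, c("weight_kg", "height_cm", "sex"))
    ref <- read_lms_reference(config$lms_path)
    fl <- whz_flags(whz_zscore(d$weight_kg, d$height_cm, d$sex, ref))
    n0 <- nrow(d)
    d$severe_wasting <- as.integer(fl$severe_wasting)
    d <- d[fl$plausible, , drop = FALSE]
    log("excluded %d of %d records with implausible z-scores", n0 - nrow(d), n0)
  } else if (config$outcome_mode == "whz") {
    check_columns(d, "whz")
    fl <- whz_flags(d$whz)
    n0 <- nrow(d)
    d$severe_wasting <- as.integer(fl$severe_wasting)
    d <- d[fl$plausible, , drop = FALSE]
    log("excluded %d of %d records with implausible z-scores", n0 - nrow(d), n0)
  } else check_columns(d, "severe_wasting")

  # wealth dichotomy: compute from assets when absent
  if (!"wealth" %in% names(d)) {
    acols <- grep("^asset_", names(d), value = TRUE)
    if (!length(acols))
      stop("no 'wealth' column and no asset_* columns to build one from",
           call. = FALSE)
    log("computing wealth index from %d asset columns", length(acols))
    wa <- compute_wealth_index(d[acols], d$weight)
    d$wealth <- wa$dichotomy
  }

  # complete cases on analysis columns
  use <- c("country", "cluster", "weight", "wealth", "severe_wasting",
           intersect(config$covariates, names(d)))
  n0 <- nrow(d)
  d <- d[stats::complete.cases(d[use]), , drop = FALSE]
  if (nrow(d) < n0) log("dropped %d incomplete records", n0 - nrow(d))

  # per-country inequality
  table1 <- summarize_table1(d, conf = config$conf,
                             variance = config$variance, log = log)
  ok <- is.finite(table1$rd) & table1$country != "All"
  meta <- pool_random_effects(table1$rd[ok], table1$se[ok],
                              labels = table1$country[ok],
                              conf = config$conf)
  quad <- classify_quadrant(table1$prev_all[ok], table1$rd[ok],
                            threshold = config$quadrant_threshold,
                            labels = table1$country[ok])
  table2 <- summarize_table2(d, intersect(config$covariates, names(d)))

  # pooled decomposition
  decomp <- oaxaca_decompose(d, "severe_wasting", config$covariates,
                             group = "wealth", weights = "weight",
                             link = config$link, type = "twofold",
                             reference = config$reference,
                             scheme = config$scheme,
                             normalization = config$normalization)
  decomp3 <- oaxaca_decompose(d, "severe_wasting", config$covariates,
                              group = "wealth", weights = "weight",
                              link = config$link, type = "threefold",
                              scheme = config$scheme,
                              normalization = config$normalization)
  boot <- NULL
  if (config$bootstrap_replicates >= 50) {
    boot <- oaxaca_bootstrap(d, "severe_wasting", config$covariates,
                             group = "wealth", weights = "weight",
                             cluster = "cluster", country = "country",
                             link = config$link, type = "twofold",
                             reference = config$reference,
                             scheme = config$scheme,
                             normalization = config$normalization,
                             replicates = config$bootstrap_replicates,
                             seed = config$seed, conf = config$conf)
  }

  by_country <- NULL
  if (config$per_country_decomposition) {
    by_country <- lapply(split(d, d$country), function(dc)
      tryCatch(oaxaca_decompose(dc, "severe_wasting", config$covariates,
                                group = "wealth", weights = "weight",
                                link = config$link, type = "twofold",
                                reference = config$reference,
                                scheme = config$scheme,
                                normalization = config$normalization),
               error = function(e) {
                 log("skipping decomposition for %s: %s",
                     dc$country[1], conditionMessage(e))
                 NULL
               }))
  }

  report <- list(table1 = table1, table2 = table2, meta = meta,
                 quadrants = quad, decomposition = decomp,
                 decomposition_threefold = decomp3,
                 decomposition_by_country = by_country,
                 bootstrap = boot, n_records = nrow(d),
                 config = config, log = log_lines)
  class(report) <- "study_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d records, %d countries\n", x$n_records,
              sum(x$table1$country != "All")))
  print(x$meta)
  print(x$decomposition)
  invisible(x)
}

#' Country summary of poverty and severe-wasting prevalence
#'
#' Per-country unweighted n, weighted severe-wasting prevalence overall
#' and by wealth group, weighted poor share, the risk difference per
#' 1000 with confidence interval, and the Breslow-Day (Tarone)
#' odds-ratio homogeneity p-value across clusters; an `All` row pools
#' every record. Numbers are kept at full precision; use
#' [format_summary_table()] for display to one decimal.
#'
#' @inheritParams rd_inference
#' @param country Country column name.
#' @param log Optional logger `function(fmt, ...)` receiving skip
#'   reasons.
#' @return Data frame, one row per country plus `All`.
#' @export
summarize_table1 <- function(records, outcome = "severe_wasting",
                             group = "wealth", weight = "weight",
                             cluster = "cluster", country = "country",
                             conf = 0.95, variance = "cluster",
                             log = function(...) invisible(NULL)) {
  check_columns(records, c(outcome, group, weight, cluster, country))
  one <- function(dd, label) {
    ri <- tryCatch(rd_inference(dd, outcome, group, weight, cluster,
                                conf, variance, country = label),
                   error = function(e) {
                     log("skipping %s: %s", label, conditionMessage(e))
                     data.frame(country = label, n = nrow(dd),
                                prev_all = weighted_prevalence(
                                  dd[[outcome]], dd[[weight]]),
                                prev_poor = NA_real_,
                                prev_nonpoor = NA_real_, rd = NA_real_,
                                se = NA_real_, lcl = NA_real_,
                                ucl = NA_real_, significant = NA)
                   })
    ri$poor_pct <- weighted_prevalence(
      as.character(dd[[group]]) == "poor", dd[[weight]], "poor share")
    ri$homogeneity_p <- tryCatch(
      homogeneity_test(strata_tables(dd, outcome, group, cluster))$p.value,
      error = function(e) NA_real_)
    ri
  }
  parts <- lapply(split(records, records[[country]]),
                  function(dd) one(dd, as.character(dd[[country]][1])))
  out <- do.call(rbind, c(parts, list(one(records, "All"))))
  rownames(out) <- NULL
  out[c("country", "n", "prev_all", "poor_pct", "prev_poor",
        "prev_nonpoor", "rd", "se", "lcl", "ucl", "significant",
        "homogeneity_p")]
}

#' Pooled covariate summary
#'
#' For every level of every covariate: weighted n, weighted percent of
#' the sample, weighted poor share, and the weighted severe-wasting
#' prevalence among the poor and the non-poor.
#'
#' @inheritParams summarize_table1
#' @param covariates Covariate columns to tabulate.
#' @return Data frame with one row per covariate level.
#' @export
summarize_table2 <- function(records, covariates,
                             outcome = "severe_wasting",
                             group = "wealth", weight = "weight") {
  check_columns(records, c(covariates, outcome, group, weight))
  w <- records[[weight]]
  y <- as.numeric(records[[outcome]])
  poor <- as.character(records[[group]]) == "poor"
  W <- sum(w)
  rows <- lapply(covariates, function(v) {
    vals <- as.character(records[[v]])
    levs <- if (is.factor(records[[v]])) levels(records[[v]])
            else sort(unique(vals))
    do.call(rbind, lapply(levs, function(l) {
      i <- vals == l
      if (!any(i))
        return(data.frame(covariate = v, level = l, weighted_n = 0,
                          pct = 0, poor_pct = NA_real_,
                          sw_poor = NA_real_, sw_nonpoor = NA_real_))
      data.frame(
        covariate = v, level = l,
        weighted_n = sum(w[i]),
        pct = 100 * sum(w[i]) / W,
        poor_pct = weighted_prevalence(poor[i], w[i], "poor share"),
        sw_poor = if (any(i & poor))
          weighted_prevalence(y[i & poor], w[i & poor], "poor") else NA_real_,
        sw_nonpoor = if (any(i & !poor))
          weighted_prevalence(y[i & !poor], w[i & !poor], "non-poor")
          else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a summary table for display
#'
#' Rounds every percentage/prevalence column to one decimal, the
#' convention of published country summary tables; counts are left
#' untouched. The machine-readable tables keep full precision.
#'
#' @param table A data frame from [summarize_table1()] or
#'   [summarize_table2()].
#' @return Data frame of character columns.
#' @export
format_summary_table <- function(table) {
  pct_cols <- intersect(c("prev_all", "poor_pct", "prev_poor",
                          "prev_nonpoor", "pct", "sw_poor", "sw_nonpoor"),
                        names(table))
  for (cc in pct_cols) table[[cc]] <- fmt_pct(table[[cc]])
  table
}

#' @noRd
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table1, file.path(dir, "table1_countries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table2, file.path(dir, "table2_covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(decomposition_tidy(report),
                   file.path(dir, "decomposition.csv"), row.names = FALSE)
  bundle <- results_bundle(report)
  jsonlite::write_json(bundle, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("swdecomp %s | R %s",
                       as.character(utils::packageVersion("swdecomp")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("config hash: %s", config_hash(report$config)),
               report$log),
             file.path(dir, "run.log"))
  for (fig in c("forest", "quadrants", "heatmap")) {
    tryCatch(save_figure(report, fig, dir),
             error = function(e) invisible(NULL))
  }
  invisible(dir)
}

#' Tidy long-format decomposition results
#' @noRd
decomposition_tidy <- function(report) {
  tidy_one <- function(d, country) {
    det <- detailed_contributions(d, by = "term")
    comps <- intersect(c("E", "C", "I", "Q", "U"), names(det))
    do.call(rbind, lapply(comps, function(cc)
      data.frame(country = country, component = cc, term = det$term,
                 estimate = det[[cc]],
                 share_of_gap = det[[paste0("share_", cc)]])))
  }
  out <- tidy_one(report$decomposition, "pooled")
  out <- rbind(out, tidy_one(report$decomposition_threefold, "pooled"))
  if (!is.null(report$decomposition_by_country)) {
    for (cn in names(report$decomposition_by_country)) {
      dd <- report$decomposition_by_country[[cn]]
      if (!is.null(dd)) out <- rbind(out, tidy_one(dd, cn))
    }
  }
  out
}

#' Machine-readable results bundle (everything the figures show)
#' @noRd
results_bundle <- function(report) {
  list(n_records = report$n_records,
       table1 = report$table1,
       table2 = report$table2,
       meta = report$meta[c("pooled", "se", "lcl", "ucl", "tau2", "k")],
       quadrants = report$quadrants,
       decomposition = list(
         twofold = c(list(gap = report$decomposition$gap,
                          Q = report$decomposition$Q,
                          U = report$decomposition$U,
                          reference = report$decomposition$reference),
                     list(detail = report$decomposition$detail_terms)),
         threefold = list(gap = report$decomposition_threefold$gap,
                          E = report$decomposition_threefold$E,
                          C = report$decomposition_threefold$C,
                          I = report$decomposition_threefold$I,
                          detail = report$decomposition_threefold$detail_terms)),
       bootstrap = if (!is.null(report$bootstrap))
         list(se = as.list(report$bootstrap$se),
              replicates = report$bootstrap$replicates))
}

#' @noRd
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), f)
  unname(tools::md5sum(f))
}

#' Forest plot of country risk differences with the pooled diamond
#'
#' @param table1 Output of [summarize_table1()].
#' @param meta Output of [pool_random_effects()].
#' @return A ggplot object.
#' @export
plot_forest <- function(table1, meta) {
  d <- table1[table1$country != "All" & is.finite(table1$rd), ]
  d$country <- stats::reorder(d$country, d$rd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rd, y = .data$country)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = meta$pooled, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lcl,
                                         xmax = .data$ucl), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Risk difference per 1000 (poor - non-poor)",
                  y = NULL,
                  title = sprintf("Pooled RD %.2f (95%% CI %.2f to %.2f)",
                                  meta$pooled, meta$lcl, meta$ucl)) +
    ggplot2::theme_minimal()
}

#' Scatter of prevalence against inequality with quadrant shading
#'
#' @param table1 Output of [summarize_table1()].
#' @param threshold High/low prevalence cut (default median).
#' @return A ggplot object.
#' @export
plot_quadrants <- function(table1, threshold = NULL) {
  d <- table1[table1$country != "All" & is.finite(table1$rd), ]
  if (is.null(threshold)) threshold <- stats::median(d$prev_all)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rd, y = .data$prev_all)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$country), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = "Risk difference per 1000 (poor - non-poor)",
                  y = "Severe-wasting prevalence (%)") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-covariate explained shares across countries
#'
#' @param report A `study_report` with per-country decompositions.
#' @return A ggplot object.
#' @export
plot_contribution_heatmap <- function(report) {
  td <- decomposition_tidy(report)
  td <- td[td$component == "Q" & td$term != "(Intercept)" &
             td$country != "pooled", ]
  if (!nrow(td)) stop("no per-country decompositions in the report",
                      call. = FALSE)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$country, y = .data$term,
                                   fill = 100 * .data$share_of_gap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", 100 * .data$share_of_gap)), size = 3) +
    ggplot2::scale_fill_gradient2(name = "% of gap") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @noRd
save_figure <- function(report, which, dir) {
  p <- switch(which,
    forest = plot_forest(report$table1, report$meta),
    quadrants = plot_quadrants(report$table1,
                               report$config$quadrant_threshold),
    heatmap = if (!is.null(report$decomposition_by_country))
      plot_contribution_heatmap(report) else return(invisible(NULL)))
  ggplot2::ggsave(file.path(dir, paste0(which, ".png")), p,
                  width = 8, height = 6, dpi = 150)
  invisible(NULL)
}
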