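# Pipeline orchestration: simulate or load data, run diagnostics,
# estimation, internal-consistency tests, efficiency accounting and the
# sample-size calculation, and render the four study tables.

#' Configure an analysis pipeline
#'
#' @param input Exactly one data source: a path to a survey CSV, a
#'   \code{"survey_dataset"}, or a \code{"simulation_config"} (in which case
#'   the data are simulated at run time).
#' @param subgroups Character vector of binary covariate names for the
#'   subgroup analyses (may be empty).
#' @param designs Optional list of two \code{\link{list_design}}s used to
#'   validate a file input.
#' @param floor_threshold,ceiling_threshold Diagnostic thresholds.
#' @param output_dir Optional directory for \code{\link{render_tables}}.
#' @param seed Optional seed overriding the one in a simulation config.
#' @param quiet Suppress stage logging.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, subgroups = character(), designs = NULL,
                            floor_threshold = 0.05, ceiling_threshold = 0.10,
                            output_dir = NULL, seed = NULL, quiet = FALSE) {
  ok <- inherits(input, "simulation_config") ||
    inherits(input, "survey_dataset") ||
    (is.character(input) && length(input) == 1L)
  if (!ok)
    stop("`input` must be a file path, a survey_dataset or a simulation_config",
         call. = FALSE)
  structure(list(input = input, subgroups = subgroups, designs = designs,
                 floor_threshold = floor_threshold,
                 ceiling_threshold = ceiling_threshold,
                 output_dir = output_dir, seed = seed, quiet = quiet),
            class = "pipeline_config")
}

#' Run the full double-list analysis pipeline
#'
#' Stage order: load/simulate and validate, assumption diagnostics,
#' per-list estimates, pooled estimate, subgroup estimates,
#' internal-consistency Wald tests, double-list efficiency, and the
#' bias-variance sample-size calculation (on list A, the convention used
#' throughout the reporting). Deterministic given the input and seed.
#'
#' @param config A \code{"pipeline_config"}, or any value accepted as its
#'   \code{input} argument.
#' @param ... Passed to \code{\link{pipeline_config}} when \code{config} is
#'   a raw input.
#' @return An object of class \code{"study_report"} with data.frame
#'   components \code{table1} (prevalence and misreporting), \code{table2}
#'   (internal consistency), \code{table3} (efficiency), \code{table4}
#'   (sample sizes), and the \code{diagnostics} report.
#' @examples
#' rep <- run_pipeline(study_preset("burkina", seed = 1), quiet = TRUE)
#' rep$table1
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config, ...)
  log_stage <- function(...) if (!config$quiet) message(sprintf(...))

  input <- config$input
  if (inherits(input, "simulation_config")) {
    if (!is.null(config$seed)) input$seed <- as.integer(config$seed)
    log_stage("simulate: n = %d, seed = %d", input$n, input$seed)
    data <- simulate_survey(input)
  } else if (is.character(input)) {
    log_stage("load: %s", input)
    data <- read_survey(input, designs = config$designs)
  } else {
    data <- validate_survey(input, designs = config$designs)
  }
  log_stage("validate: %d respondents", nrow(data))
  long <- to_long(data)

  log_stage("diagnostics")
  diagnostics <- run_diagnostics(data,
                                 floor_threshold = config$floor_threshold,
                                 ceiling_threshold = config$ceiling_threshold)

  log_stage("estimation: per-list and pooled (%d long rows)", nrow(long))
  est_a <- estimate_single_list(long, "A")
  est_b <- estimate_single_list(long, "B")
  est_p <- estimate_pooled(long)
  direct_mean <- mean(data$direct_report)
  n <- nrow(data)

  t1_row <- function(est, scope_label) {
    w <- wald_vs_direct(est, direct_mean = direct_mean, n = n)
    data.frame(scope = scope_label, n_obs = est$n_obs,
               mean_treated = est$arm_means[["treated"]],
               mean_control = est$arm_means[["control"]],
               estimate = est$beta, se = est$se,
               ci_low = est$ci95[1L], ci_high = est$ci95[2L],
               direct = direct_mean, misreporting = w$misreporting,
               p_value = w$p_value, stringsAsFactors = FALSE)
  }
  table1 <- rbind(t1_row(est_a, "List A"), t1_row(est_b, "List B"),
                  t1_row(est_p, "Lists A & B"))

  log_stage("subgroups and internal consistency (%d subgroup(s))",
            length(config$subgroups))
  sub_rows <- function(subgroup) {
    w <- wald_equal_lists(long, subgroup = subgroup)
    n_sub <- sum(data[[subgroup]] == 1, na.rm = TRUE)
    data.frame(scope = subgroup, n = n_sub,
               prevalence_A = w$beta_A, se_A = w$se_A,
               prevalence_B = w$beta_B, se_B = w$se_B,
               difference = w$difference, p_value = w$p_value,
               stringsAsFactors = FALSE)
  }
  w_all <- wald_equal_lists(long)
  table2 <- data.frame(scope = "All observations", n = n,
                       prevalence_A = w_all$beta_A, se_A = w_all$se_A,
                       prevalence_B = w_all$beta_B, se_B = w_all$se_B,
                       difference = w_all$difference, p_value = w_all$p_value,
                       stringsAsFactors = FALSE)
  for (s in config$subgroups) table2 <- rbind(table2, sub_rows(s))

  log_stage("efficiency")
  # reductions recompute from the per-list SEs reported above: table 1 for
  # the full sample, table 2 for the subgroups
  eff_row <- function(scope_label, pooled_est, se_a, se_b, n_obs) {
    data.frame(scope = scope_label, n_obs = n_obs,
               prevalence = pooled_est$beta, se = pooled_est$se,
               reduction_vs_A = se_reduction(pooled_est$se, se_a),
               reduction_vs_B = se_reduction(pooled_est$se, se_b),
               stringsAsFactors = FALSE)
  }
  table3 <- eff_row("All observations", est_p, est_a$se, est_b$se, est_p$n_obs)
  for (i in seq_along(config$subgroups)) {
    s <- config$subgroups[i]
    sub_long <- long[!is.na(long[[s]]) & long[[s]] == 1, , drop = FALSE]
    ep <- estimate_pooled(sub_long)
    table3 <- rbind(table3, eff_row(s, ep, table2$se_A[i + 1L],
                                    table2$se_B[i + 1L], ep$n_obs))
  }

  log_stage("sample size (list A)")
  t4_row <- function(scope_label, est, d_sub) {
    dm <- mean(d_sub$direct_report)
    nn <- nrow(d_sub)
    prob <- bias_from_estimates(est, direct_mean = dm)
    res <- if (prob$bias > 0) nmin_solve(prob) else NULL
    data.frame(scope = scope_label, var_y0 = prob$var_y0,
               pi_star = prob$pi_star, se_list = est$se,
               direct_mean = dm, se_direct = sqrt(dm * (1 - dm) / nn),
               bias = prob$bias,
               n_min = if (is.null(res)) NA_integer_ else res$n_min,
               n_survey = nn, stringsAsFactors = FALSE)
  }
  table4 <- t4_row("All observations", est_a, data)
  for (s in config$subgroups) {
    d_sub <- data[!is.na(data[[s]]) & data[[s]] == 1, , drop = FALSE]
    ea <- estimate_single_list(to_long(d_sub), "A")
    table4 <- rbind(table4, t4_row(s, ea, d_sub))
  }

  report <- structure(list(table1 = table1, table2 = table2, table3 = table3,
                           table4 = table4, diagnostics = diagnostics,
                           n_respondents = n),
                      class = "study_report")
  if (!is.null(config$output_dir))
    render_tables(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Double-list study report (%d respondents)\n\n", x$n_respondents))
  cat("Prevalence and misreporting:\n")
  print.data.frame(x$table1, digits = 3, row.names = FALSE)
  cat("\nInternal consistency (list B - list A):\n")
  print.data.frame(x$table2, digits = 3, row.names = FALSE)
  cat("\nDouble-list efficiency:\n")
  print.data.frame(x$table3, digits = 3, row.names = FALSE)
  cat("\nBias-variance minimum sample size (list A):\n")
  print.data.frame(x$table4, digits = 3, row.names = FALSE)
  invisible(x)
}

fmt_num <- function(x) {
  if (is.numeric(x) && !all(x == round(x), na.rm = TRUE))
    sprintf("%.3f", round(x, 3))   # round first so text matches rounded CSV
  else format(x)
}

#' Render the study tables to files
#'
#' Writes one file per table. CSV keeps full precision; the text format
#' displays 3 decimals for proportions and standard errors, integers for
#' counts, and renders p-values below 0.001 as \code{"<0.001"}.
#'
#' @param report A \code{"study_report"}.
#' @param dir Output directory (created if needed).
#' @param format \code{"csv"}, \code{"text"}, or both.
#' @return Character vector of the files written, invisibly.
#' @export
render_tables <- function(report, dir, format = c("csv", "text")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("table1", "table2", "table3", "table4")) {
    tab <- report[[nm]]
    if ("csv" %in% format) {
      f <- file.path(dir, paste0(nm, ".csv"))
      full <- tab
      for (cn in names(full))   # full precision, exact numeric round-trip
        if (is.numeric(full[[cn]]) && !all(full[[cn]] == round(full[[cn]]), na.rm = TRUE))
          full[[cn]] <- sprintf("%.17g", full[[cn]])
      write.csv(full, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    if ("text" %in% format) {
      f <- file.path(dir, paste0(nm, ".txt"))
      disp <- tab
      for (cn in names(disp)) {
        if (cn == "p_value") {
          disp[[cn]] <- vapply(disp[[cn]], format_p, "")
        } else if (is.numeric(disp[[cn]])) {
          disp[[cn]] <- fmt_num(disp[[cn]])
        }
      }
      writeLines(c(paste(names(disp), collapse = "\t"),
                   apply(disp, 1L, paste, collapse = "\t")), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
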