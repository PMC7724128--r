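#' Validate a wide respondent table
#'
#' Checks the structural invariants of a double-list survey table: required
#' columns, unique respondent ids, group labels in \code{{1, 2}}, no missing
#' counts or groups, and count bounds (0..J on the control list, 0..J+1 on
#' the treated list; group 1 is treated on list A, group 2 on list B).
#'
#' @param data A data.frame with columns \code{respondent_id}, \code{group},
#'   \code{y_listA}, \code{y_listB}, \code{direct_report}.
#' @param designs List of two \code{\link{list_design}}s giving J per list;
#'   taken from \code{attr(data, "designs")} if absent, else J = 3.
#' @return The validated data, classed \code{"survey_dataset"}, invisibly
#'   usable downstream. Errors list the offending rows.
#' @export
validate_survey <- function(data, designs = NULL) {
  required <- c("respondent_id", "group", "y_listA", "y_listB", "direct_report")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(designs)) designs <- attr(data, "designs")
  if (is.null(designs)) designs <- list(list_design("A"), list_design("B"))
  J <- designs[[1L]]$J

  dup <- duplicated(data$respondent_id)
  if (any(dup))
    stop("duplicate respondent_id in row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  if (anyNA(data$group) || !all(data$group %in% c(1L, 2L)))
    stop("`group` must be 1 or 2 with no missing values; offending row(s): ",
         paste(which(is.na(data$group) | !data$group %in% c(1L, 2L)),
               collapse = ", "), call. = FALSE)

  check_bounds <- function(y, treated, lab) {
    if (anyNA(y))
      stop(sprintf("missing %s count in row(s): %s", lab,
                   paste(which(is.na(y)), collapse = ", ")), call. = FALSE)
    upper <- ifelse(treated, J + 1L, J)
    bad <- which(y < 0 | y > upper | y != round(y))
    if (length(bad))
      stop(sprintf("%s count out of range (0..J on control, 0..J+1 on treated) in row(s): %s",
                   lab, paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_bounds(data$y_listA, data$group == 1L, "y_listA")
  check_bounds(data$y_listB, data$group == 2L, "y_listB")

  if (anyNA(data$direct_report) || !all(data$direct_report %in% c(0L, 1L)))
    stop("`direct_report` must be 0/1 with no missing values; offending row(s): ",
         paste(which(is.na(data$direct_report) |
                       !data$direct_report %in% c(0L, 1L)), collapse = ", "),
         call. = FALSE)

  if (is.null(data$treated_list))
    data$treated_list <- ifelse(data$group == 1L, "A", "B")
  attr(data, "designs") <- designs
  if (!inherits(data, "survey_dataset"))
    class(data) <- c("survey_dataset", class(data))
  data
}

#' Read a respondent table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing at
#' least \code{respondent_id, group, y_listA, y_listB, direct_report};
#' additional columns are kept as covariates. The table is validated with
#' \code{\link{validate_survey}}.
#'
#' @param path Path to the CSV file.
#' @param designs List of two \code{\link{list_design}}s (defaults: J = 3).
#' @return A \code{"survey_dataset"}.
#' @export
read_survey <- function(path, designs = NULL) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  validate_survey(data, designs = designs)
}

#' Write a respondent table to CSV
#'
#' @param data A \code{"survey_dataset"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_survey <- function(data, path) {
  write.csv(as.data.frame(data)[, setdiff(names(data), character(0))],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reshape a wide respondent table to long (respondent x list) layout
#'
#' The long layout stacks one row per respondent and list, carrying the item
#' count \code{Y}, the treatment indicator \code{T} (1 on the respondent's
#' treated list), the list label, and a list-A indicator used as the design
#' control in pooled regressions. Covariates and the direct report are
#' carried along. Rows with a missing count (single-list studies) are
#' dropped.
#'
#' @param data A \code{"survey_dataset"}.
#' @return A \code{data.frame} of class \code{"long_dataset"} with 2n rows
#'   (double-list data) and exactly one treated row per respondent.
#' @examples
#' cfg <- simulation_config(n = 8, behavior = behavior_model(0.5), seed = 1)
#' to_long(simulate_survey(cfg))
#' @export
to_long <- function(data) {
  covars <- setdiff(names(data),
                    c("respondent_id", "group", "y_listA", "y_listB",
                      "treated_list", "direct_report"))
  one <- function(lab, y) {
    out <- data.frame(respondent_id = data$respondent_id,
                      list = rep(lab, nrow(data)),
                      Y = y,
                      T = as.integer((data$group == 1L) == (lab == "A")),
                      list_A_flag = rep(as.integer(lab == "A"), nrow(data)),
                      direct_report = data$direct_report,
                      stringsAsFactors = FALSE)
    for (nm in covars) out[[nm]] <- data[[nm]]
    out
  }
  long <- rbind(one("A", data$y_listA), one("B", data$y_listB))
  long <- long[!is.na(long$Y), , drop = FALSE]
  long <- long[order(long$respondent_id, long$list), , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "designs") <- attr(data, "designs")
  class(long) <- c("long_dataset", "data.frame")
  long
}

#' Reshape a long table back to the wide respondent layout
#'
#' Inverse of \code{\link{to_long}} for double-list data.
#'
#' @param long A \code{"long_dataset"}.
#' @return A \code{"survey_dataset"}.
#' @export
to_wide <- function(long) {
  a <- long[long$list == "A", , drop = FALSE]
  b <- long[long$list == "B", , drop = FALSE]
  a <- a[order(a$respondent_id), , drop = FALSE]
  b <- b[order(b$respondent_id), , drop = FALSE]
  if (!identical(a$respondent_id, b$respondent_id))
    stop("long data are not complete double-list data (a respondent is missing a list)",
         call. = FALSE)
  covars <- setdiff(names(long),
                    c("respondent_id", "list", "Y", "T", "list_A_flag",
                      "direct_report"))
  out <- data.frame(respondent_id = a$respondent_id,
                    group = ifelse(a$T == 1L, 1L, 2L),
                    y_listA = a$Y,
                    y_listB = b$Y,
                    treated_list = ifelse(a$T == 1L, "A", "B"),
                    direct_report = a$direct_report,
                    stringsAsFactors = FALSE)
  for (nm in covars) out[[nm]] <- a[[nm]]
  attr(out, "designs") <- attr(long, "designs")
  class(out) <- c("survey_dataset", "data.frame")
  out
}

# Expand categorical covariates to 0/1 indicators (reference = modal level);
# binary 0/1 or logical columns pass through. Returns a plain data.frame of
# numeric indicator columns.
expand_covariates <- function(data, covariates) {
  out <- list()
  for (nm in covariates) {
    x <- data[[nm]]
    if (is.null(x)) stop(sprintf("unknown covariate '%s'", nm), call. = FALSE)
    if (is.logical(x)) x <- as.integer(x)
    if (is.numeric(x) && all(x[!is.na(x)] %in% c(0, 1))) {
      out[[nm]] <- as.numeric(x)
    } else if (is.numeric(x)) {
      out[[nm]] <- as.numeric(x)
    } else {
      lev <- names(sort(table(x), decreasing = TRUE))
      for (l in lev[-1L])
        out[[paste(nm, l, sep = "_")]] <- as.numeric(x == l)
    }
  }
  as.data.frame(out, optional = TRUE)
}
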