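# Assumption diagnostics: randomisation balance, design effects (shifts of
# the non-sensitive answers when the sensitive item is present), and
# ceiling/floor pressure in the control arm.

#' Randomisation balance test
#'
#' Compares covariate means between the two arrival-parity groups with
#' two-sample z tests (unpooled variances, normal reference), plus a joint
#' F test of all covariates in a linear model of the group indicator.
#' Constant covariates are skipped with a warning. Categorical covariates
#' are expanded to indicators (reference level = most frequent).
#'
#' @param data A \code{"survey_dataset"}.
#' @param covariates Character vector of covariate column names; defaults to
#'   every column that is not part of the survey core.
#' @return An object of class \code{"balance_table"}: a data.frame with one
#'   row per covariate (group means, difference, SE, z, p) and the joint
#'   test p-value as attribute \code{"joint_p"}.
#' @export
balance_test <- function(data, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(data),
                          c("respondent_id", "group", "y_listA", "y_listB",
                            "treated_list", "direct_report"))
  if (!length(covariates)) stop("at least one covariate is required", call. = FALSE)
  X <- expand_covariates(data, covariates)
  keep <- vapply(X, function(x) stats::sd(x, na.rm = TRUE) > 0, TRUE)
  if (any(!keep))
    warning("skipping constant covariate(s): ",
            paste(names(X)[!keep], collapse = ", "), call. = FALSE)
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no non-constant covariates to test", call. = FALSE)
  g1 <- data$group == 1L
  rows <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    m1 <- mean(x[g1], na.rm = TRUE); m2 <- mean(x[!g1], na.rm = TRUE)
    v1 <- var(x[g1], na.rm = TRUE) / sum(g1 & !is.na(x))
    v2 <- var(x[!g1], na.rm = TRUE) / sum(!g1 & !is.na(x))
    se <- sqrt(v1 + v2)
    z <- if (se > 0) (m1 - m2) / se else 0
    data.frame(covariate = nm, mean_group1 = m1, mean_group2 = m2,
               difference = m1 - m2, se = se, z = z,
               p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  df <- cbind(g = as.numeric(g1), X)
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(g ~ ., data = df)
  fs <- suppressWarnings(summary(fit))$fstatistic
  joint_p <- if (is.null(fs)) NA_real_
             else unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  attr(tab, "joint_p") <- joint_p
  class(tab) <- c("balance_table", "data.frame")
  tab
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  cat("Randomisation balance (group 1 vs group 2):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("Joint F test p-value: %s\n", format_p(attr(x, "joint_p"))))
  invisible(x)
}

ecdf_at <- function(y, points) vapply(points, function(p) mean(y <= p), 0)

#' Design-effect test for one list
#'
#' If adding the sensitive item does not change answers to the non-sensitive
#' items, the control and treated count distributions must satisfy, for
#' every count y: (1) \code{Pr(Y <= y | control) >= Pr(Y <= y | treated)}
#' for y = 0..J, and (2) \code{Pr(Y <= y | treated) >= Pr(Y <= y-1 |
#' control)} for y = 1..J+1. Each inequality gets a one-sided z statistic
#' for violation (unpooled binomial variances across arms, normal
#' reference); the summary is the Bonferroni-corrected minimum p,
#' \code{min(1, 2(J+1) * min p)}. The inequality (2) at y = J+1 is vacuous
#' (both CDFs equal 1) and reported with p = 1.
#'
#' @param data A \code{"long_dataset"} (or \code{"survey_dataset"}).
#' @param list \code{"A"} or \code{"B"}.
#' @param J Number of non-sensitive items (default from the attached design,
#'   else 3).
#' @return An object of class \code{"design_effect_test"}: a data.frame with
#'   one row per inequality (inequality label, y, CDF values, violation, z,
#'   one-sided p) and attributes \code{"min_p"}, \code{"bonferroni_p"},
#'   \code{"m"}.
#' @export
design_effect_test <- function(data, list = c("A", "B"), J = NULL) {
  list <- match.arg(list)
  d <- subset_list(data, list)
  if (is.null(J)) {
    des <- attr(data, "designs")
    J <- if (!is.null(des)) des[[1L]]$J else 3L
  }
  y0 <- d$Y[d$T == 0L]; y1 <- d$Y[d$T == 1L]
  n0 <- length(y0); n1 <- length(y1)
  if (n0 < 2L || n1 < 2L)
    stop("insufficient data: each arm needs at least 2 observations", call. = FALSE)

  one_sided <- function(violation, f_a, n_a, f_b, n_b) {
    se <- sqrt(f_a * (1 - f_a) / n_a + f_b * (1 - f_b) / n_b)
    if (se == 0) return(c(z = if (violation > 0) Inf else 0,
                          p = if (violation > 0) 0 else 1))
    z <- violation / se
    c(z = z, p = pnorm(z, lower.tail = FALSE))
  }

  F0 <- ecdf_at(y0, 0:J)          # F0(0..J)
  F1 <- ecdf_at(y1, 0:(J + 1L))   # F1(0..J+1)
  rows <- list()
  for (y in 0:J) {                # (1): F0(y) >= F1(y); violation F1 - F0
    r <- one_sided(F1[y + 1L] - F0[y + 1L], F0[y + 1L], n0, F1[y + 1L], n1)
    rows[[length(rows) + 1L]] <-
      data.frame(inequality = "control_dominates", y = y,
                 cdf_control = F0[y + 1L], cdf_treated = F1[y + 1L],
                 violation = F1[y + 1L] - F0[y + 1L], z = r["z"], p_value = r["p"])
  }
  for (y in 1:(J + 1L)) {         # (2): F1(y) >= F0(y-1); violation F0(y-1) - F1(y)
    if (y == J + 1L) {            # both CDFs are 1: vacuous
      rows[[length(rows) + 1L]] <-
        data.frame(inequality = "treated_dominates_shifted", y = y,
                   cdf_control = 1, cdf_treated = 1, violation = 0,
                   z = 0, p_value = 1)
      next
    }
    r <- one_sided(F0[y] - F1[y + 1L], F0[y], n0, F1[y + 1L], n1)
    rows[[length(rows) + 1L]] <-
      data.frame(inequality = "treated_dominates_shifted", y = y,
                 cdf_control = F0[y], cdf_treated = F1[y + 1L],
                 violation = F0[y] - F1[y + 1L], z = r["z"], p_value = r["p"])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  m <- 2L * (J + 1L)
  attr(tab, "min_p") <- min(tab$p_value)
  attr(tab, "bonferroni_p") <- min(1, m * min(tab$p_value))
  attr(tab, "m") <- m
  attr(tab, "list") <- list
  class(tab) <- c("design_effect_test", "data.frame")
  tab
}

#' @export
print.design_effect_test <- function(x, digits = 3, ...) {
  cat(sprintf("Design-effect test, list %s (%d inequalities):\n",
              attr(x, "list"), nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("Bonferroni-corrected minimum p: %s\n",
              format_p(attr(x, "bonferroni_p"))))
  invisible(x)
}

#' Ceiling and floor proportions in the control arm
#'
#' Respondents who agree with all (ceiling) or none (floor) of the
#' non-sensitive items would reveal their sensitive answer when treated, so
#' the control-arm proportions at the two ends of the count scale should be
#' small. Flags are raised above 5\% (floor) and 10\% (ceiling) by default,
#' the bands within which the original surveys fell.
#'
#' @param data A \code{"long_dataset"} (or \code{"survey_dataset"}).
#' @param list \code{"A"} or \code{"B"}.
#' @param J Number of non-sensitive items (default from design, else 3).
#' @param floor_threshold,ceiling_threshold Warning thresholds.
#' @return A list with \code{floor_prop}, \code{ceiling_prop},
#'   \code{floor_flag}, \code{ceiling_flag}, \code{n_control}.
#' @export
ceiling_floor <- function(data, list = c("A", "B"), J = NULL,
                          floor_threshold = 0.05, ceiling_threshold = 0.10) {
  list <- match.arg(list)
  d <- subset_list(data, list)
  if (is.null(J)) {
    des <- attr(data, "designs")
    J <- if (!is.null(des)) des[[1L]]$J else 3L
  }
  y0 <- d$Y[d$T == 0L]
  if (!length(y0)) stop("control arm is empty", call. = FALSE)
  floor_prop <- mean(y0 == 0L)
  ceiling_prop <- mean(y0 == J)
  list(floor_prop = floor_prop, ceiling_prop = ceiling_prop,
       floor_flag = floor_prop > floor_threshold,
       ceiling_flag = ceiling_prop > ceiling_threshold,
       n_control = length(y0), list = list, J = J)
}

#' Run all assumption diagnostics
#'
#' Bundles the balance test, the per-list design-effect tests and the
#' per-list ceiling/floor proportions into one report.
#'
#' @param data A \code{"survey_dataset"}.
#' @param covariates Covariates for the balance test (default: all).
#' @param floor_threshold,ceiling_threshold Passed to
#'   \code{\link{ceiling_floor}}.
#' @return An object of class \code{"diagnostics_report"}.
#' @export
run_diagnostics <- function(data, covariates = NULL,
                            floor_threshold = 0.05, ceiling_threshold = 0.10) {
  long <- to_long(data)
  balance <- tryCatch(balance_test(data, covariates),
                      error = function(e) NULL)
  de <- lapply(c(A = "A", B = "B"), function(l) design_effect_test(long, l))
  cf <- lapply(c(A = "A", B = "B"), function(l)
    ceiling_floor(long, l, floor_threshold = floor_threshold,
                  ceiling_threshold = ceiling_threshold))
  structure(list(balance = balance, design_effect = de, ceiling_floor = cf),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  if (!is.null(x$balance)) print(x$balance) else
    cat("Balance test: no covariates available.\n")
  for (l in names(x$design_effect)) {
    cat(sprintf("\nList %s: Bonferroni-corrected design-effect p = %s; ",
                l, format_p(attr(x$design_effect[[l]], "bonferroni_p"))))
    cf <- x$ceiling_floor[[l]]
    cat(sprintf("floor %.3f%s, ceiling %.3f%s (n control = %d)\n",
                cf$floor_prop, if (cf$floor_flag) " [FLAG]" else "",
                cf$ceiling_prop, if (cf$ceiling_flag) " [FLAG]" else "",
                cf$n_control))
  }
  invisible(x)
}
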