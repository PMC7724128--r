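# Covariance machinery -------------------------------------------------------

# HC1 heteroskedasticity-robust, classical, or respondent-clustered (CR1,
# small-sample factor G/(G-1) * (N-1)/(N-K), the survey-econometrics default)
vcov_for <- function(fit, se_flavor, cluster = NULL) {
  switch(se_flavor,
         classical = vcov(fit),
         robust = sandwich::vcovHC(fit, type = "HC1"),
         cluster = sandwich::vcovCL(fit, cluster = cluster, type = "HC1",
                                    cadjust = TRUE),
         stop("unknown se_flavor: ", se_flavor, call. = FALSE))
}

new_prevalence_estimate <- function(beta, lambda, se, n_obs, scope, clustered,
                                    se_flavor, arm_means = c(NA_real_, NA_real_),
                                    var_y0 = NA_real_, n_control = NA_integer_,
                                    fit = NULL, cluster = NULL) {
  structure(list(beta = beta, lambda = lambda, se = se,
                 ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
                 n_obs = n_obs, scope = scope, clustered = clustered,
                 se_flavor = se_flavor, arm_means = arm_means,
                 var_y0 = var_y0, n_control = n_control,
                 fit = fit, cluster = cluster),
            class = "prevalence_estimate")
}

#' Construct a prevalence estimate from reported numbers
#'
#' Builds a \code{"prevalence_estimate"} directly from a published point
#' estimate and standard error, so that the Wald tests and the sample-size
#' tools can be applied to printed results without the underlying microdata.
#'
#' @param beta Prevalence estimate (treated-minus-control mean difference).
#' @param se Its standard error.
#' @param n_obs Number of observations behind the estimate.
#' @param lambda Optional control-arm mean (intercept).
#' @param scope \code{"list A"}, \code{"list B"} or \code{"pooled"}.
#' @return A \code{"prevalence_estimate"}.
#' @examples
#' prevalence_estimate(0.800, 0.062, 495, scope = "list A")
#' @export
prevalence_estimate <- function(beta, se, n_obs, lambda = NA_real_,
                                scope = "list A") {
  stopifnot(is.numeric(beta), is.numeric(se), se >= 0, n_obs > 0)
  new_prevalence_estimate(beta, lambda, se, as.integer(n_obs), scope,
                          clustered = FALSE, se_flavor = "reported")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Prevalence estimate (%s%s): %.3f  SE %.3f  95%% CI [%.3f; %.3f]  n = %d\n",
              x$scope, if (x$clustered) ", respondent-clustered SE" else "",
              x$beta, x$se, x$ci95[1L], x$ci95[2L], x$n_obs))
  invisible(x)
}

subset_list <- function(data, list) {
  if (inherits(data, "survey_dataset")) data <- to_long(data)
  out <- data[data$list == list, , drop = FALSE]
  if (!nrow(out)) stop("no observations for list ", list, call. = FALSE)
  out
}

# Estimators ------------------------------------------------------------------

#' Single-list prevalence estimator
#'
#' Regresses the item count \code{Y} on the treatment indicator \code{T} for
#' one list. With a single binary regressor, OLS returns exactly the
#' treated-minus-control difference in mean counts, which identifies the
#' prevalence of the sensitive behaviour; the intercept is the control-arm
#' mean. Default standard errors are heteroskedasticity-robust (HC1): the
#' treated arm adds a Bernoulli term, so arm variances differ by
#' construction.
#'
#' @param data A \code{"long_dataset"} (or a \code{"survey_dataset"}, which
#'   is reshaped internally).
#' @param list \code{"A"} or \code{"B"}.
#' @param se_flavor \code{"robust"} (default) or \code{"classical"}.
#' @return A \code{"prevalence_estimate"} carrying, besides the estimate,
#'   the arm means and the control-arm count variance \code{var_y0} used by
#'   the sample-size tools.
#' @examples
#' cfg <- study_preset("burkina", seed = 3)
#' long <- to_long(simulate_survey(cfg))
#' estimate_single_list(long, "A")
#' @export
estimate_single_list <- function(data, list = c("A", "B"),
                                 se_flavor = c("robust", "classical")) {
  list <- match.arg(list)
  se_flavor <- match.arg(se_flavor)
  d <- subset_list(data, list)
  if (length(unique(d$T)) < 2L)
    stop("degenerate design: both treated and control observations are required",
         call. = FALSE)
  fit <- lm(Y ~ T, data = d)
  V <- vcov_for(fit, se_flavor)
  y0 <- d$Y[d$T == 0L]
  new_prevalence_estimate(
    beta = unname(coef(fit)["T"]), lambda = unname(coef(fit)["(Intercept)"]),
    se = sqrt(V["T", "T"]), n_obs = nrow(d), scope = paste("list", list),
    clustered = FALSE, se_flavor = se_flavor,
    arm_means = c(treated = mean(d$Y[d$T == 1L]), control = mean(y0)),
    var_y0 = var(y0), n_control = length(y0),
    fit = fit, cluster = d$respondent_id)
}

#' Pooled double-list prevalence estimator
#'
#' Stacks both lists and regresses \code{Y} on \code{T} plus a list-A
#' indicator that absorbs the level difference between the two lists.
#' Because every respondent contributes a treated and a control observation,
#' standard errors are clustered at the respondent level by default. With
#' equal group sizes the pooled estimate equals the arithmetic mean of the
#' two single-list estimates exactly.
#'
#' @param data A double-list \code{"long_dataset"} (or \code{"survey_dataset"}).
#' @param se_flavor \code{"cluster"} (default), \code{"robust"} or
#'   \code{"classical"}.
#' @return A \code{"prevalence_estimate"} with scope \code{"pooled"}.
#' @export
estimate_pooled <- function(data, se_flavor = c("cluster", "robust", "classical")) {
  se_flavor <- match.arg(se_flavor)
  if (inherits(data, "survey_dataset")) data <- to_long(data)
  if (!all(c("A", "B") %in% data$list))
    stop("pooled estimation needs observations from both lists", call. = FALSE)
  fit <- lm(Y ~ T + list_A_flag, data = data)
  V <- vcov_for(fit, se_flavor, cluster = data$respondent_id)
  y0 <- data$Y[data$T == 0L]
  new_prevalence_estimate(
    beta = unname(coef(fit)["T"]), lambda = unname(coef(fit)["(Intercept)"]),
    se = sqrt(V["T", "T"]), n_obs = nrow(data), scope = "pooled",
    clustered = se_flavor == "cluster", se_flavor = se_flavor,
    arm_means = c(treated = mean(data$Y[data$T == 1L]), control = mean(y0)),
    var_y0 = var(y0), n_control = length(y0),
    fit = fit, cluster = data$respondent_id)
}

#' Subgroup (interaction) prevalence estimator
#'
#' Adds a binary subgroup indicator \code{S} and its interaction with the
#' treatment to the prevalence regression. \code{beta} is the prevalence in
#' the \code{S = 0} subgroup, \code{beta + alpha} the prevalence in the
#' \code{S = 1} subgroup (the saturated-model identity: each equals the
#' within-subgroup difference in arm means in the single-list case). The
#' pooled variant adds the list-A indicator and clusters by respondent.
#'
#' @param data A \code{"long_dataset"} (or \code{"survey_dataset"}).
#' @param subgroup Name of a binary covariate column.
#' @param list \code{"A"}, \code{"B"}, or \code{NULL} for the pooled model.
#' @param se_flavor Defaults to \code{"cluster"} when pooled, else
#'   \code{"robust"}.
#' @return An object of class \code{"subgroup_estimate"} with components
#'   \code{beta}, \code{gamma}, \code{alpha}, \code{prevalence_S1},
#'   standard errors and 95\% CIs for \code{beta} and \code{beta + alpha}.
#' @export
estimate_subgroup <- function(data, subgroup, list = NULL, se_flavor = NULL) {
  if (inherits(data, "survey_dataset")) data <- to_long(data)
  pooled <- is.null(list)
  d <- if (pooled) data else subset_list(data, match.arg(list, c("A", "B")))
  if (is.null(se_flavor)) se_flavor <- if (pooled) "cluster" else "robust"
  S <- d[[subgroup]]
  if (is.null(S)) stop(sprintf("unknown covariate '%s'", subgroup), call. = FALSE)
  if (anyNA(S)) {
    keep <- !is.na(S)
    message(sprintf("dropping %d observation(s) with missing '%s' (listwise deletion)",
                    sum(!keep), subgroup))
    d <- d[keep, , drop = FALSE]
    S <- S[keep]
  }
  if (!all(S %in% c(0, 1)))
    stop("`subgroup` must be a binary 0/1 covariate", call. = FALSE)
  cells <- table(factor(S, levels = 0:1), factor(d$T, levels = 0:1))
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("degenerate design: empty cell S=%s, T=%s",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]),
         call. = FALSE)
  }
  d$S <- as.numeric(S)
  fit <- if (pooled) lm(Y ~ T + S + T:S + list_A_flag, data = d)
         else lm(Y ~ T + S + T:S, data = d)
  V <- vcov_for(fit, se_flavor, cluster = d$respondent_id)
  b <- coef(fit)
  beta <- unname(b["T"]); alpha <- unname(b["T:S"])
  se_beta <- sqrt(V["T", "T"])
  se_s1 <- sqrt(V["T", "T"] + V["T:S", "T:S"] + 2 * V["T", "T:S"])
  structure(list(beta = beta, gamma = unname(b["S"]), alpha = alpha,
                 lambda = unname(b["(Intercept)"]),
                 prevalence_S1 = beta + alpha,
                 se_beta = se_beta, se_S1 = se_s1,
                 ci95_beta = c(beta - 1.96 * se_beta, beta + 1.96 * se_beta),
                 ci95_S1 = c(beta + alpha - 1.96 * se_s1,
                             beta + alpha + 1.96 * se_s1),
                 n_obs = nrow(d), subgroup = subgroup,
                 scope = if (pooled) "pooled" else paste("list", list),
                 se_flavor = se_flavor, fit = fit, cluster = d$respondent_id),
            class = "subgroup_estimate")
}

#' @export
print.subgroup_estimate <- function(x, ...) {
  cat(sprintf("Subgroup estimate (%s, S = %s):\n", x$scope, x$subgroup))
  cat(sprintf("  prevalence | S=0: %.3f (SE %.3f)\n", x$beta, x$se_beta))
  cat(sprintf("  prevalence | S=1: %.3f (SE %.3f)   interaction alpha: %.3f\n",
              x$prevalence_S1, x$se_S1, x$alpha))
  invisible(x)
}

# Wald tests ------------------------------------------------------------------

new_wald_result <- function(difference, se_diff, method, extra = list()) {
  statistic <- if (se_diff > 0) difference / se_diff
               else if (difference == 0) 0 else sign(difference) * Inf
  p <- 2 * pnorm(-abs(statistic))
  structure(c(list(difference = difference, se_diff = se_diff,
                   statistic = statistic, p_value = p, method = method),
              extra),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald test (%s): difference %.3f  SE %.3f  z = %.3f  p = %s\n",
              x$method, x$difference, x$se_diff, x$statistic,
              format_p(x$p_value)))
  invisible(x)
}

#' Internal-consistency Wald test between the two lists
#'
#' Tests whether the two single-list prevalence estimates agree
#' (\code{beta_B = beta_A}). The default operates on respondent-level data
#' via a stacked regression with list-specific treatment effects and a
#' respondent-clustered covariance, which accounts for the fact that the
#' same respondents enter both estimates in opposite roles. Alternatively,
#' two already-computed (e.g. published) estimates can be compared under an
#' independence assumption: \code{se_diff = sqrt(se_A^2 + se_B^2)}.
#'
#' @param data A double-list \code{"long_dataset"} (or
#'   \code{"survey_dataset"}); may be \code{NULL} when \code{est_a} and
#'   \code{est_b} are supplied.
#' @param subgroup Optional binary covariate; the comparison is then run on
#'   the \code{S = 1} respondents (their within-subgroup prevalences, equal
#'   to \code{beta + alpha} of the interaction model by saturation).
#' @param est_a,est_b Optional \code{"prevalence_estimate"}s for the
#'   independent-variance comparison.
#' @param method \code{"stacked"} (default with data) or
#'   \code{"independent"}.
#' @return A \code{"wald_result"} with the difference \code{beta_B - beta_A}.
#' @examples
#' # from published numbers:
#' wald_equal_lists(est_a = prevalence_estimate(0.800, 0.062, 495),
#'                  est_b = prevalence_estimate(0.793, 0.058, 495, scope = "list B"))
#' @export
wald_equal_lists <- function(data = NULL, subgroup = NULL,
                             est_a = NULL, est_b = NULL,
                             method = c("stacked", "independent")) {
  method <- match.arg(method)
  if (is.null(data)) {
    if (is.null(est_a) || is.null(est_b))
      stop("either `data` or both `est_a` and `est_b` must be supplied",
           call. = FALSE)
    diff <- est_b$beta - est_a$beta
    return(new_wald_result(diff, sqrt(est_a$se^2 + est_b$se^2), "independent",
                           list(beta_A = est_a$beta, beta_B = est_b$beta,
                                se_A = est_a$se, se_B = est_b$se)))
  }
  if (inherits(data, "survey_dataset")) data <- to_long(data)
  if (!all(c("A", "B") %in% data$list))
    stop("unsupported design: internal-consistency test needs both lists",
         call. = FALSE)
  if (!is.null(subgroup)) {
    S <- data[[subgroup]]
    if (is.null(S)) stop(sprintf("unknown covariate '%s'", subgroup), call. = FALSE)
    data <- data[!is.na(S) & S == 1, , drop = FALSE]
  }
  if (method == "independent") {
    ea <- estimate_single_list(data, "A")
    eb <- estimate_single_list(data, "B")
    return(new_wald_result(eb$beta - ea$beta, sqrt(ea$se^2 + eb$se^2),
                           "independent",
                           list(beta_A = ea$beta, beta_B = eb$beta,
                                se_A = ea$se, se_B = eb$se)))
  }
  d <- data
  d$T_A <- d$T * d$list_A_flag
  d$T_B <- d$T * (1L - d$list_A_flag)
  fit <- lm(Y ~ list_A_flag + T_A + T_B, data = d)
  V <- vcov_for(fit, "cluster", cluster = d$respondent_id)
  b <- coef(fit)
  diff <- unname(b["T_B"] - b["T_A"])
  se <- sqrt(V["T_A", "T_A"] + V["T_B", "T_B"] - 2 * V["T_A", "T_B"])
  new_wald_result(diff, se, "stacked-clustered",
                  list(beta_A = unname(b["T_A"]), beta_B = unname(b["T_B"]),
                       se_A = sqrt(V["T_A", "T_A"]),
                       se_B = sqrt(V["T_B", "T_B"]),
                       n = nrow(d)))
}

#' Wald test of the list estimate against the direct self-report
#'
#' Quantifies misreporting: the difference between the direct-question
#' proportion and the list-experiment prevalence, with a two-sided normal
#' test of zero difference. The default treats the two estimates as
#' independent, \code{se_diff = sqrt(se_beta^2 + p(1-p)/n)}; the
#' \code{"stacked"} method instead estimates the covariance between the two
#' statistics from respondent-level influence functions (the same people
#' answer both instruments).
#'
#' @param est A \code{"prevalence_estimate"} (fitted, or built from printed
#'   numbers with \code{\link{prevalence_estimate}}).
#' @param data A \code{"survey_dataset"} supplying \code{direct_report};
#'   alternatively pass \code{direct_mean} and \code{n} directly.
#' @param direct_mean,n Direct-question proportion and its sample size, used
#'   when \code{data} is absent.
#' @param method \code{"independent"} (default) or \code{"stacked"}.
#' @return A \code{"wald_result"} with \code{difference = direct - beta} and
#'   the misreporting magnitude \code{|difference|} as \code{misreporting}.
#' @examples
#' est <- prevalence_estimate(0.800, 0.062, 495)
#' wald_vs_direct(est, direct_mean = 0.968, n = 495)  # p about 0.007
#' @export
wald_vs_direct <- function(est, data = NULL, direct_mean = NULL, n = NULL,
                           method = c("independent", "stacked")) {
  method <- match.arg(method)
  if (!inherits(est, "prevalence_estimate"))
    stop("`est` must be a `prevalence_estimate`", call. = FALSE)
  if (est$beta < -0.2 || est$beta > 1.2)
    warning("list estimate far outside [0, 1]; interpret with caution (estimator noise)",
            call. = FALSE)
  if (is.null(direct_mean)) {
    if (is.null(data)) stop("supply `data` or `direct_mean` and `n`", call. = FALSE)
    direct <- data$direct_report
    direct_mean <- mean(direct)
    n <- length(direct)
  }
  diff <- direct_mean - est$beta
  if (method == "independent" || is.null(est$fit)) {
    if (method == "stacked")
      stop("the stacked method needs a fitted estimate (with stored regression)",
           call. = FALSE)
    se <- sqrt(est$se^2 + direct_mean * (1 - direct_mean) / n)
    return(new_wald_result(diff, se, "independent",
                           list(direct_mean = direct_mean, beta = est$beta,
                                misreporting = abs(diff), n_direct = n)))
  }
  # respondent-level influence functions: psi_g(direct) - psi_g(beta)
  if (is.null(data)) stop("the stacked method needs respondent-level `data`",
                          call. = FALSE)
  fit <- est$fit
  X <- model.matrix(fit)
  e <- residuals(fit)
  bread <- solve(crossprod(X))
  a_obs <- drop(X %*% bread[, "T"]) * e          # per-observation influence on beta
  A_g <- rowsum(a_obs, est$cluster)
  d_g <- data$direct_report[match(as.numeric(rownames(A_g)), data$respondent_id)]
  if (anyNA(d_g))
    stop("`data` does not cover all respondents used in the estimate", call. = FALSE)
  psi <- (d_g - direct_mean) / length(d_g) - drop(A_g)
  G <- length(psi)
  se <- sqrt(sum(psi^2) * G / (G - 1))
  new_wald_result(diff, se, "stacked-clustered",
                  list(direct_mean = direct_mean, beta = est$beta,
                       misreporting = abs(diff), n_direct = length(d_g)))
}

format_p <- function(p, text = TRUE) {
  if (text && p < 0.001) "<0.001" else sprintf("%.3f", p)
}
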