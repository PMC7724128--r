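# Double-list efficiency accounting and the bias-variance minimum sample
# size: the N above which the list experiment's MSE (unbiased but noisy)
# falls below the direct question's MSE (precise but biased by B).

#' Relative change in standard error from pooling the two lists
#'
#' \code{(se_double - se_single) / se_single}; negative values are
#' efficiency gains (multiply by 100 for percent display).
#'
#' @param se_double SE of the pooled double-list estimate.
#' @param se_single SE of a single-list estimate.
#' @return The relative change (a fraction).
#' @examples
#' se_reduction(0.038, 0.062)  # -0.387
#' @export
se_reduction <- function(se_double, se_single) {
  if (!is.numeric(se_single) || any(se_single <= 0))
    stop("`se_single` must be positive", call. = FALSE)
  if (!is.numeric(se_double) || any(se_double < 0))
    stop("`se_double` must be non-negative", call. = FALSE)
  (se_double - se_single) / se_single
}

#' Specify a bias-variance sample-size problem
#'
#' The three quantities that drive the trade-off: the true prevalence
#' \code{pi_star} (taken to be the list-experiment estimate), the variance
#' \code{var_y0} of the control-arm item count, and the absolute
#' misreporting bias \code{B} of the direct question (derived as
#' \code{|direct_mean - pi_star|} when not given).
#'
#' @param pi_star Assumed true prevalence, in (0, 1).
#' @param var_y0 Control-arm item-count variance, >= 0.
#' @param direct_mean Self-declared prevalence in \code{[0, 1]} (optional if
#'   \code{bias} is given).
#' @param bias Absolute bias B > 0 of the direct question (optional if
#'   \code{direct_mean} is given).
#' @return An object of class \code{"samplesize_problem"}.
#' @export
sample_size_problem <- function(pi_star, var_y0, direct_mean = NULL, bias = NULL) {
  if (!is.numeric(pi_star) || pi_star <= 0 || pi_star >= 1)
    stop("`pi_star` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(var_y0) || var_y0 < 0)
    stop("`var_y0` must be non-negative", call. = FALSE)
  if (is.null(bias)) {
    if (is.null(direct_mean))
      stop("supply `bias` or `direct_mean`", call. = FALSE)
    bias <- abs(direct_mean - pi_star)
  } else if (!is.null(direct_mean) &&
             abs(bias - abs(direct_mean - pi_star)) > 1e-8) {
    warning("`bias` disagrees with |direct_mean - pi_star|; using `bias`",
            call. = FALSE)
  }
  structure(list(pi_star = pi_star, var_y0 = var_y0,
                 direct_mean = direct_mean, bias = bias),
            class = "samplesize_problem")
}

#' Minimum sample size for the list experiment to beat the direct question
#'
#' Solves the quadratic in \code{x = N - 1} at which the mean-squared errors
#' of the two instruments cross: with \code{y = B} and
#' \code{C = pi_star (1 - pi_star) + 4 var_y0},
#' \deqn{y^2 x^2 + [(2 \pi^* - 1) y - 4 Var(Y(0))] x - C = 0.}
#' The positive root \code{x} gives \code{N_min = round(x) + 1} (nearest
#' integer; coefficients are kept at full precision throughout). Above
#' \code{N_min} the list experiment, whose variance shrinks like
#' \code{C/(N-1)}, has lower MSE than the direct question, whose squared
#' bias \code{B^2} does not shrink.
#'
#' @param problem A \code{"samplesize_problem"}, or the prevalence
#'   \code{pi_star} when the remaining pieces are passed explicitly.
#' @param var_y0,bias,direct_mean Used when \code{problem} is numeric.
#' @return An object of class \code{"samplesize_result"} with the quadratic
#'   coefficients (\code{quad_a}, \code{quad_b}, \code{quad_c}), \code{C},
#'   the positive root \code{root_x} and \code{n_min}.
#' @examples
#' nmin_solve(sample_size_problem(0.800, 0.673, bias = 0.168))  # n_min = 94
#' @export
nmin_solve <- function(problem, var_y0 = NULL, bias = NULL, direct_mean = NULL) {
  if (!inherits(problem, "samplesize_problem"))
    problem <- sample_size_problem(problem, var_y0, direct_mean, bias)
  y <- problem$bias
  if (y <= 0)
    stop("no finite solution: with zero bias the direct question always wins asymptotically",
         call. = FALSE)
  pi_star <- problem$pi_star
  C <- pi_star * (1 - pi_star) + 4 * problem$var_y0
  a <- y^2
  b <- (2 * pi_star - 1) * y - 4 * problem$var_y0
  cc <- -C
  disc <- b^2 - 4 * a * cc
  root_x <- (-b + sqrt(disc)) / (2 * a)   # the other root is negative (c < 0)
  structure(list(quad_a = a, quad_b = b, quad_c = cc, C = C,
                 root_x = root_x, n_min = as.integer(round(root_x + 1)),
                 problem = problem),
            class = "samplesize_result")
}

#' @export
print.samplesize_result <- function(x, ...) {
  cat(sprintf("Minimum sample size: N_min = %d\n", x$n_min))
  cat(sprintf("  quadratic %.6f x^2 + %.6f x + %.6f = 0, root x = %.3f (C = %.3f)\n",
              x$quad_a, x$quad_b, x$quad_c, x$root_x, x$C))
  cat(sprintf("  inputs: pi* = %.3f, Var[Y(0)] = %.3f, B = %.3f\n",
              x$problem$pi_star, x$problem$var_y0, x$problem$bias))
  invisible(x)
}

#' Build a sample-size problem from a fitted estimate
#'
#' Takes the list-experiment estimate as the assumed true prevalence and the
#' direct-question proportion as the self-declared rate, giving
#' \code{B = |direct_mean - beta|}; the control-arm variance comes from the
#' estimate itself (stored at fit time) unless overridden.
#'
#' @param list_estimate A \code{"prevalence_estimate"}.
#' @param direct_mean Self-declared prevalence.
#' @param var_y0 Optional control-arm variance override.
#' @return A \code{"samplesize_problem"}.
#' @export
bias_from_estimates <- function(list_estimate, direct_mean, var_y0 = NULL) {
  if (!inherits(list_estimate, "prevalence_estimate"))
    stop("`list_estimate` must be a `prevalence_estimate`", call. = FALSE)
  beta <- list_estimate$beta
  if (beta < 0 || beta > 1) {
    warning("list estimate outside [0, 1]; clamped (sampling noise)", call. = FALSE)
    beta <- min(max(beta, 0), 1)
  }
  if (is.null(var_y0)) var_y0 <- list_estimate$var_y0
  if (is.null(var_y0) || is.na(var_y0))
    stop("`var_y0` is not stored in the estimate; supply it explicitly",
         call. = FALSE)
  sample_size_problem(beta, var_y0, direct_mean = direct_mean)
}
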