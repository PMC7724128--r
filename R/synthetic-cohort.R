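#' Describe a list of non-sensitive items
#'
#' A list design records the agreement probability of each non-sensitive
#' item. Implementation guidelines for list experiments recommend including
#' one item that most respondents agree with and one that most disagree
#' with, so that treated respondents at neither end of the count scale lose
#' the privacy of their answer; a design satisfying
#' \code{max(item_probs) >= 0.8} and \code{min(item_probs) <= 0.2} is marked
#' guideline-compliant.
#'
#' @param list_id Label of the list, e.g. \code{"A"} or \code{"B"}.
#' @param item_probs Numeric vector of per-item agreement probabilities in
#'   \code{[0, 1]}; length is the number of non-sensitive items J (J = 3 in
#'   the designs this package emulates). Default \code{c(0.9, 0.5, 0.1)}:
#'   one high-agreement item, one middling, one low-agreement item.
#' @param sensitive_position Ordinal position at which the sensitive item is
#'   read to treated respondents (presentation only; the count is order
#'   invariant). Defaults to last.
#' @return An object of class \code{"list_design"}.
#' @examples
#' list_design("A")
#' list_design("B", item_probs = c(0.85, 0.4, 0.15))
#' @export
list_design <- function(list_id, item_probs = c(0.9, 0.5, 0.1),
                        sensitive_position = length(item_probs) + 1L) {
  if (!is.character(list_id) || length(list_id) != 1L)
    stop("`list_id` must be a single label", call. = FALSE)
  if (length(item_probs) < 2L)
    stop("a list needs at least two non-sensitive items (J >= 2)", call. = FALSE)
  if (any(!is.finite(item_probs)) || any(item_probs < 0) || any(item_probs > 1))
    stop("`item_probs` must lie in [0, 1]", call. = FALSE)
  structure(
    list(list_id = list_id,
         item_probs = as.numeric(item_probs),
         J = length(item_probs),
         sensitive_position = as.integer(sensitive_position),
         guideline_compliant = max(item_probs) >= 0.8 && min(item_probs) <= 0.2),
    class = "list_design")
}

#' @export
print.list_design <- function(x, ...) {
  cat(sprintf("List %s: %d non-sensitive items, agreement probs (%s)%s\n",
              x$list_id, x$J, paste(format(x$item_probs), collapse = ", "),
              if (x$guideline_compliant) ", guideline-compliant" else ""))
  invisible(x)
}

#' True-prevalence model of the sensitive behaviour
#'
#' @param pi True prevalence of the sensitive behaviour, in \code{[0, 1]}.
#' @param subgroup_effects Optional named numeric vector of additive
#'   prevalence shifts attached to binary covariates: a respondent with
#'   covariate \code{x = 1} has prevalence \code{pi + subgroup_effects["x"]}
#'   (clamped to \code{[0, 1]}).
#' @return An object of class \code{"behavior_model"}.
#' @export
behavior_model <- function(pi, subgroup_effects = NULL) {
  if (!is.numeric(pi) || length(pi) != 1L || pi < 0 || pi > 1)
    stop("`pi` must be a probability in [0, 1]", call. = FALSE)
  if (!is.null(subgroup_effects) &&
      (is.null(names(subgroup_effects)) || any(!nzchar(names(subgroup_effects)))))
    stop("`subgroup_effects` must be a named numeric vector", call. = FALSE)
  structure(list(pi = pi, subgroup_effects = subgroup_effects),
            class = "behavior_model")
}

#' Misreporting model for the direct question
#'
#' Social desirability bias distorts the direct self-report only; list
#' answers are assumed truthful (the count protects privacy). Under
#' over-reporting (e.g. condom use) a respondent without the trait claims it
#' with probability \code{q}, so \code{E(direct) = pi + q (1 - pi)}; under
#' under-reporting (e.g. intimate partner violence) a respondent with the
#' trait denies it with probability \code{q}, so \code{E(direct) = pi (1 - q)}.
#'
#' @param direction \code{"under_report"} or \code{"over_report"}.
#' @param q Misreport probability in \code{[0, 1]}.
#' @return An object of class \code{"misreport_model"}.
#' @export
misreport_model <- function(direction = c("under_report", "over_report"), q = 0) {
  direction <- match.arg(direction)
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
    stop("`q` must be a probability in [0, 1]", call. = FALSE)
  structure(list(direction = direction, q = q), class = "misreport_model")
}

#' Controlled violations of the list-experiment assumptions
#'
#' With the all-default (null) settings the three identifying assumptions --
#' randomisation balance, no design effect, no ceiling/floor pressure --
#' hold by construction in the simulator; the fields below inject specific
#' violations so the diagnostics can be validated.
#'
#' @param design_effect_shift Additive change (possibly negative) applied to
#'   every non-sensitive item agreement probability for \emph{treated}
#'   respondents, i.e. the presence of the sensitive item changes answers to
#'   the other items. Shifted probabilities are clamped to \code{[0, 1]}
#'   with a warning.
#' @param liar_mode \code{"none"}, or \code{"deflate_at_ceiling"}: a treated
#'   respondent holding the sensitive trait who would report the maximum
#'   count J + 1 (thus revealing the trait) reports J instead.
#' @return An object of class \code{"violation_config"}.
#' @export
violation_config <- function(design_effect_shift = 0,
                             liar_mode = c("none", "deflate_at_ceiling")) {
  liar_mode <- match.arg(liar_mode)
  if (!is.numeric(design_effect_shift) || length(design_effect_shift) != 1L ||
      !is.finite(design_effect_shift))
    stop("`design_effect_shift` must be a finite number", call. = FALSE)
  structure(list(design_effect_shift = design_effect_shift, liar_mode = liar_mode),
            class = "violation_config")
}

#' Full configuration of a synthetic double-list survey
#'
#' @param n Number of respondents (at least 4).
#' @param designs List of two \code{\link{list_design}} objects (lists A and B).
#' @param behavior A \code{\link{behavior_model}}.
#' @param misreport A \code{\link{misreport_model}}.
#' @param violations A \code{\link{violation_config}}.
#' @param covariates List of covariate specifications; each element is a list
#'   with fields \code{name}, \code{type} (\code{"binary"} or
#'   \code{"categorical"}) and either \code{p} (binary success probability)
#'   or \code{levels}/\code{probs} (categorical).
#' @param respondent_sd Standard deviation of a respondent-level agreement
#'   propensity added to every non-sensitive item probability on both lists
#'   (clamped to \code{[0, 1]}). It induces the positive within-respondent
#'   correlation of item counts across lists that field data exhibit, which
#'   drives the double-list efficiency gain beyond the 1 - 1/sqrt(2) bound
#'   of the independence model. Set to 0 for fully independent item answers.
#' @param seed Integer seed; the same seed yields an identical dataset.
#' @return An object of class \code{"simulation_config"}.
#' @seealso \code{\link{study_preset}} for ready-made configurations
#'   emulating the Senegal and Burkina Faso study designs.
#' @export
simulation_config <- function(n,
                              designs = list(list_design("A"), list_design("B")),
                              behavior = behavior_model(0.5),
                              misreport = misreport_model("under_report", 0),
                              violations = violation_config(),
                              covariates = list(),
                              respondent_sd = 0.15,
                              seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n))
    stop("`n` must be an integer >= 4", call. = FALSE)
  if (length(designs) != 2L || !all(vapply(designs, inherits, TRUE, "list_design")))
    stop("`designs` must be a list of two `list_design` objects", call. = FALSE)
  if (designs[[1L]]$J != designs[[2L]]$J)
    stop("both lists must have the same number of non-sensitive items", call. = FALSE)
  stopifnot(inherits(behavior, "behavior_model"),
            inherits(misreport, "misreport_model"),
            inherits(violations, "violation_config"))
  if (!is.numeric(respondent_sd) || respondent_sd < 0)
    stop("`respondent_sd` must be a non-negative number", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  for (cv in covariates) {
    if (is.null(cv$name) || is.null(cv$type) ||
        !cv$type %in% c("binary", "categorical"))
      stop("each covariate spec needs `name` and `type` in {binary, categorical}",
           call. = FALSE)
  }
  structure(list(n = as.integer(n), designs = designs, behavior = behavior,
                 misreport = misreport, violations = violations,
                 covariates = covariates, respondent_sd = respondent_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Alternating group assignment by arrival order
#'
#' Respondents are allocated by the parity of their arrival number: odd
#' arrivals form group 1 (treated on list A, control on list B), even
#' arrivals group 2 (the reverse). The arrival order is outside the
#' enumerator's control, so the assignment is as good as random.
#'
#' @param n Number of respondents.
#' @return Integer vector of group labels in \code{{1, 2}}.
#' @examples
#' assign_groups(4)  # 1 2 1 2
#' @export
assign_groups <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  rep_len(c(1L, 2L), n)
}

clamp01 <- function(p, what) {
  out <- p < 0 | p > 1
  if (any(out))
    warning(sprintf("%d %s value(s) outside [0, 1] were clamped", sum(out), what),
            call. = FALSE)
  pmin(pmax(p, 0), 1)
}

gen_covariate <- function(cv, n) {
  if (cv$type == "binary") {
    if (is.null(cv$p)) stop("binary covariate spec needs `p`", call. = FALSE)
    rbinom(n, 1L, cv$p)
  } else {
    if (is.null(cv$levels)) stop("categorical covariate spec needs `levels`", call. = FALSE)
    probs <- if (is.null(cv$probs)) rep(1 / length(cv$levels), length(cv$levels)) else cv$probs
    sample(cv$levels, n, replace = TRUE, prob = probs)
  }
}

#' Simulate a double-list experiment survey
#'
#' Generates one row per respondent. Each respondent carries a latent
#' sensitive trait \code{Z ~ Bernoulli(pi_i)} (with \code{pi_i} shifted by
#' any subgroup effects), answers every non-sensitive item independently
#' Bernoulli given a respondent-level agreement propensity, and reports the
#' per-list counts: the count on the treated list (determined by group
#' parity) includes \code{Z}. The direct question reports \code{Z} distorted
#' by the misreporting model. Assumption violations are injected per the
#' \code{\link{violation_config}}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{data.frame} of class \code{"survey_dataset"} with columns
#'   \code{respondent_id}, \code{group}, \code{y_listA}, \code{y_listB},
#'   \code{treated_list}, \code{direct_report}, followed by covariates. The
#'   list designs are attached as attribute \code{"designs"}.
#' @examples
#' cfg <- simulation_config(n = 100, behavior = behavior_model(0.3), seed = 7)
#' head(simulate_survey(cfg))
#' @export
simulate_survey <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must be a `simulation_config`", call. = FALSE)
  set.seed(config$seed)
  n <- config$n
  J <- config$designs[[1L]]$J
  group <- assign_groups(n)
  treated_list <- ifelse(group == 1L, "A", "B")

  cov_df <- list()
  for (cv in config$covariates) cov_df[[cv$name]] <- gen_covariate(cv, n)

  pi_i <- rep(config$behavior$pi, n)
  eff <- config$behavior$subgroup_effects
  if (!is.null(eff)) {
    for (nm in names(eff)) {
      if (is.null(cov_df[[nm]]))
        stop(sprintf("subgroup effect refers to unknown covariate '%s'", nm),
             call. = FALSE)
      pi_i <- pi_i + eff[[nm]] * as.numeric(cov_df[[nm]])
    }
    pi_i <- clamp01(pi_i, "per-respondent prevalence")
  }
  z <- rbinom(n, 1L, pi_i)

  # shared agreement propensity: correlates item counts within a respondent
  u <- if (config$respondent_sd > 0) rnorm(n, 0, config$respondent_sd) else numeric(n)

  shift <- config$violations$design_effect_shift
  counts <- list()
  for (d in config$designs) {
    lab <- d$list_id
    treated <- treated_list == lab
    probs <- matrix(d$item_probs, n, J, byrow = TRUE) + u
    if (shift != 0) {
      if (any(d$item_probs + shift < 0 | d$item_probs + shift > 1))
        warning(sprintf("list %s: shifted item probabilities outside [0, 1] were clamped",
                        lab), call. = FALSE)
      probs[treated, ] <- probs[treated, ] + shift
    }
    probs <- pmin(pmax(probs, 0), 1)  # propensity clamping is routine, silent
    agree <- matrix(rbinom(n * J, 1L, probs), n, J)
    y <- rowSums(agree)
    y[treated] <- y[treated] + z[treated]
    if (config$violations$liar_mode == "deflate_at_ceiling") {
      at_ceiling <- treated & z == 1L & y == J + 1L
      y[at_ceiling] <- y[at_ceiling] - 1L
    }
    counts[[lab]] <- as.integer(y)
  }

  q <- config$misreport$q
  direct <- z
  if (q > 0) {
    if (config$misreport$direction == "under_report") {
      deny <- z == 1L & rbinom(n, 1L, q) == 1L
      direct[deny] <- 0L
    } else {
      claim <- z == 0L & rbinom(n, 1L, q) == 1L
      direct[claim] <- 1L
    }
  }

  out <- data.frame(respondent_id = seq_len(n),
                    group = group,
                    y_listA = counts[["A"]],
                    y_listB = counts[["B"]],
                    treated_list = treated_list,
                    direct_report = as.integer(direct),
                    stringsAsFactors = FALSE)
  for (nm in names(cov_df)) out[[nm]] <- cov_df[[nm]]
  attr(out, "designs") <- config$designs
  class(out) <- c("survey_dataset", "data.frame")
  out
}

#' Ready-made configurations emulating the two study designs
#'
#' \code{"senegal"}: condom use among female sex workers in Dakar
#' (n = 495, true prevalence 0.80, direct self-report about 0.968, i.e.
#' over-reporting with q = 0.84). \code{"burkina"}: physical intimate
#' partner violence among partnered women in rural Burkina Faso (n = 1706,
#' true prevalence 0.24, direct self-report about 0.054, i.e.
#' under-reporting with q = 0.775). Both use two lists of three
#' non-sensitive items with a guideline-compliant agreement profile
#' (0.9, 0.5, 0.1) and a couple of binary covariates with marginals close to
#' the surveyed samples.
#'
#' @param study \code{"senegal"} or \code{"burkina"}.
#' @param seed Integer seed.
#' @param n Optional override of the number of respondents.
#' @return A \code{\link{simulation_config}}.
#' @examples
#' cfg <- study_preset("burkina", seed = 42)
#' mean(simulate_survey(cfg)$direct_report)  # about 0.054
#' @export
study_preset <- function(study = c("senegal", "burkina"), seed = 1L, n = NULL) {
  study <- match.arg(study)
  if (study == "senegal") {
    simulation_config(
      n = if (is.null(n)) 495L else n,
      behavior = behavior_model(0.80),
      misreport = misreport_model("over_report", q = 0.84),
      covariates = list(
        list(name = "registered", type = "binary", p = 0.506),
        list(name = "high_hiv_knowledge", type = "binary", p = 0.828)),
      seed = seed)
  } else {
    simulation_config(
      n = if (is.null(n)) 1706L else n,
      behavior = behavior_model(0.24),
      misreport = misreport_model("under_report", q = 0.775),
      covariates = list(
        list(name = "polygamous", type = "binary", p = 0.253),
        list(name = "attended_school", type = "binary", p = 0.245)),
      seed = seed)
  }
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the arguments of \code{\link{simulation_config}}; the
#' seed is mandatory (in the file or via the \code{seed} argument).
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the one in the file.
#' @return A \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n`/`y` key as a boolean; recover the intent
  names(y)[names(y) == "FALSE"] <- "n"
  if (is.null(y$n)) y$n <- y$n_respondents
  if (is.null(seed)) seed <- y$seed
  if (is.null(seed)) stop("a seed must be given in the file or as an argument",
                          call. = FALSE)
  designs <- if (is.null(y$designs)) {
    list(list_design("A"), list_design("B"))
  } else {
    lapply(y$designs, function(d)
      list_design(d$list_id, item_probs = as.numeric(d$item_probs)))
  }
  mis <- if (is.null(y$misreport)) misreport_model("under_report", 0)
         else misreport_model(y$misreport$direction, y$misreport$q)
  beh <- behavior_model(y$pi,
                        subgroup_effects = if (!is.null(y$subgroup_effects))
                          unlist(y$subgroup_effects))
  vio <- if (is.null(y$violations)) violation_config()
         else violation_config(
           design_effect_shift = if (is.null(y$violations$design_effect_shift)) 0
                                 else y$violations$design_effect_shift,
           liar_mode = if (is.null(y$violations$liar_mode)) "none"
                       else y$violations$liar_mode)
  simulation_config(
    n = y$n, designs = designs, behavior = beh, misreport = mis,
    violations = vio,
    covariates = if (is.null(y$covariates)) list() else y$covariates,
    respondent_sd = if (is.null(y$respondent_sd)) 0.15 else y$respondent_sd,
    seed = seed)
}
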