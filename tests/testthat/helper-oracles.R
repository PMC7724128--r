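# Independent oracles used across the tests: exhaustive enumeration for
# small item sets, brute-force linear algebra, grid searches. They never
# call the implementation paths they check.

# Poisson-binomial pmf over 0..J by exhaustive enumeration of agreement patterns
pb_pmf <- function(probs) {
  J <- length(probs)
  pat <- as.matrix(expand.grid(rep(list(0:1), J)))
  pr <- apply(pat, 1L, function(b) prod(ifelse(b == 1, probs, 1 - probs)))
  tapply(pr, rowSums(pat), sum)
}

# expected treated-list mean under the ceiling-deflation liar mode
enum_liar_treated_mean <- function(pi, probs) {
  J <- length(probs)
  sum(probs) + pi - pi * pb_pmf(probs)[[as.character(J)]]
}

# OLS by explicit normal equations
ols_normal_eq <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# cluster-robust (CR1) covariance by hand, Stata-style small-sample factor
cr1_vcov <- function(fit, cluster) {
  X <- model.matrix(fit)
  e <- residuals(fit)
  M <- rowsum(X * e, cluster)
  G <- nrow(M); N <- nrow(X); K <- ncol(X)
  br <- solve(crossprod(X))
  G / (G - 1) * (N - 1) / (N - K) * br %*% crossprod(M) %*% br
}

# brute-force MSE-crossover: smallest N at which the list experiment's MSE
# C/(N-1) drops below the direct question's B^2 + p(1-p)/N, p = pi - B
mse_crossover <- function(pi, var_y0, B, n_max = 20000L) {
  C <- pi * (1 - pi) + 4 * var_y0
  p <- pi - B
  N <- 2:n_max
  hit <- which(C / (N - 1) <= B^2 + p * (1 - p) / N)
  if (!length(hit)) stop("no crossover below n_max")
  N[hit[1L]]
}

# integer count vector of length n with exact mean m (values floor/ceiling of m)
vec_with_mean <- function(n, m) {
  tot <- round(n * m)
  stopifnot(abs(tot - n * m) < 1e-9)
  b <- tot %/% n
  r <- tot - b * n
  c(rep(b + 1L, r), rep(b, n - r))
}

# long single-list fixture from explicit arm values
long_fixture <- function(y_control, y_treated, list = "A") {
  n0 <- length(y_control); n1 <- length(y_treated)
  structure(data.frame(respondent_id = seq_len(n0 + n1),
                       list = list,
                       Y = c(y_control, y_treated),
                       T = rep(c(0L, 1L), c(n0, n1)),
                       list_A_flag = as.integer(list == "A"),
                       direct_report = 0L),
            class = c("long_dataset", "data.frame"))
}

# balanced double-list wide fixture with exact per-list arm means
wide_fixture <- function(n_half, mean_tA, mean_cA, mean_tB, mean_cB) {
  data.frame(respondent_id = seq_len(2L * n_half),
             group = rep(c(1L, 2L), each = n_half),
             y_listA = c(vec_with_mean(n_half, mean_tA),
                         vec_with_mean(n_half, mean_cA)),
             y_listB = c(vec_with_mean(n_half, mean_cB),
                         vec_with_mean(n_half, mean_tB)),
             direct_report = 0L)
}

strip_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "designs") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}
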