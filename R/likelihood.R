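#' Marginal log-likelihood of the Beta mixture IRM
#'
#' Evaluates the observed-data log-likelihood with the class indicator
#' marginalized out: for each response cell,
#' `log(pi_i * f_att(y_ij) + (1 - pi_i) * f_care(y_ij))` computed by
#' log-sum-exp, where `f_att` is the conditional Beta IRM density and
#' `f_care` the common careless Beta(m, n) density.  This is the same
#' quantity the sampler targets; the pure-R form exists as the readable
#' reference.
#'
#' @param responses numeric person-by-item matrix with entries strictly in
#'   (0, 1); `NA` cells are skipped.
#' @param params a list with elements `items` (an [item_params] table with
#'   the current difficulty/dispersion values), `theta` (person-by-dimension
#'   matrix, or vector for one dimension), `m`, `n` (careless shapes) and
#'   `person_prob` (per-person attentiveness probabilities; a scalar is
#'   recycled).
#' @return the scalar log-likelihood.
#' @export
mixture_log_likelihood <- function(responses, params) {
  y <- as.matrix(responses)
  if (any(y <= 0 | y >= 1, na.rm = TRUE))
    stop("responses must lie strictly inside (0, 1)", call. = FALSE)
  items <- as_item_params(params$items)
  theta <- params$theta
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1)
  N <- nrow(y)
  pii <- rep_len(params$person_prob, N)
  total <- 0
  for (i in seq_len(N)) {
    keep <- !is.na(y[i, ])
    if (!any(keep)) next
    la <- beta_irm_log_density(y[i, keep], theta[i, ], items[keep, ])
    lc <- careless_log_density(y[i, keep], params$m, params$n)
    hi <- pmax(log(pii[i]) + la, log1p(-pii[i]) + lc)
    total <- total + sum(hi + log(exp(log(pii[i]) + la - hi) +
                                  exp(log1p(-pii[i]) + lc - hi)))
  }
  total
}

#' Joint log-prior of the Beta mixture IRM parameters
#'
#' Sums the log-densities of the full prior stack: normal priors on item
#' difficulties and dispersions, half-Cauchy priors on trait SDs and on the
#' careless shapes m and n, an LKJ prior on the trait correlation matrix
#' (proper normalizing constant omitted; only log-prior differences matter
#' for sampling), the hierarchical Beta (two-class Dirichlet) prior on each
#' person's attentiveness probability, a flat Dirichlet(1, 1) prior on the
#' population attentive proportion, and a half-Cauchy prior on the
#' concentration.  Parameters outside their support yield `-Inf` rather than
#' an error, so the function can serve directly as a rejection target.
#'
#' @param params a list with elements `items` (difficulty/dispersion),
#'   `trait_sd` (vector), `trait_corr` (correlation matrix; optional when
#'   unidimensional), `m`, `n`, `attentive_prop`, `concentration`, and
#'   `person_prob`.
#' @param prior a [prior_config].
#' @return scalar log-prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params, prior = prior_config()) {
  items <- params$items
  lp <- sum(stats::dnorm(items$difficulty, 0, prior$item_prior_sd, log = TRUE)) +
        sum(stats::dnorm(items$dispersion, 0, prior$item_prior_sd, log = TRUE))

  sig <- params$trait_sd
  if (any(sig <= 0)) return(-Inf)
  lp <- lp + sum(half_cauchy_lpdf(sig, prior$trait_sd_scale))

  R <- params$trait_corr
  if (!is.null(R) && length(sig) > 1L) {
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8))
      return(-Inf)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return(-Inf)
    lp <- lp + (prior$lkj_shape - 1) * determinant(R)$modulus[1]
  }

  if (params$m <= 0 || params$n <= 0) return(-Inf)
  lp <- lp + half_cauchy_lpdf(params$m, prior$careless_shape_scale) +
             half_cauchy_lpdf(params$n, prior$careless_shape_scale)

  p <- params$attentive_prop
  if (p <= 0 || p >= 1) return(-Inf)
  lp <- lp + stats::dbeta(p, prior$dirichlet_base[1], prior$dirichlet_base[2],
                          log = TRUE)

  om <- params$concentration
  if (om <= 0) return(-Inf)
  lp <- lp + half_cauchy_lpdf(om, prior$concentration_scale)

  pii <- params$person_prob
  if (any(pii <= 0 | pii >= 1)) return(-Inf)
  # two-class Dirichlet(omega*pi, omega*(1-pi)) reduces to a Beta density
  lp + sum(stats::dbeta(pii, om * p, om * (1 - p), log = TRUE))
}

#' Posterior probability that a response row is attentive
#'
#' Bayes-rule diagnostic for a whole response row at fixed parameter values:
#' `pi_i * prod_j f_att / (pi_i * prod_j f_att + (1 - pi_i) * prod_j f_care)`,
#' computed in log space.
#'
#' @param y_row numeric vector of one person's responses, strictly in (0, 1);
#'   `NA` cells are skipped.
#' @param params as in [mixture_log_likelihood]; `person_prob` may be a
#'   scalar or indexed by `person`.
#' @param person index of the person whose trait vector and prior probability
#'   to use.
#' @return the posterior attentive probability in (0, 1).
#' @export
posterior_class_probability <- function(y_row, params, person = 1L) {
  if (any(y_row <= 0 | y_row >= 1, na.rm = TRUE))
    stop("responses must lie strictly inside (0, 1)", call. = FALSE)
  items <- as_item_params(params$items)
  theta <- params$theta
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1)
  pii <- rep_len(params$person_prob, max(person, length(params$person_prob)))
  keep <- !is.na(y_row)
  la <- log(pii[person]) +
    sum(beta_irm_log_density(y_row[keep], theta[person, ], items[keep, ]))
  lc <- log1p(-pii[person]) +
    sum(careless_log_density(y_row[keep], params$m, params$n))
  hi <- max(la, lc)
  exp(la - hi) / (exp(la - hi) + exp(lc - hi))
}

#' Log-likelihood of the normal mixture CFA baseline
#'
#' The comparison model applies a one-factor normal CFA mixture to bounded
#' responses: attentive cells are `Normal(nu_j + lambda_j * theta_i, sigma_j)`
#' and careless cells are `Normal(mu_c, sigma_c)`.  The model deliberately
#' ignores the bounded support of the data; its failure on Beta-generated
#' responses is the point of carrying it.
#'
#' @param responses numeric person-by-item matrix (any real values; `NA`
#'   skipped).
#' @param params list with `intercept`, `loading`, `residual_sd` (per item),
#'   `trait` (per person, scalar dimension), `careless_mean`, `careless_sd`,
#'   `person_prob`.
#' @return scalar log-likelihood (`-Inf` for non-positive SDs).
#' @export
cfa_mixture_log_likelihood <- function(responses, params) {
  y <- as.matrix(responses)
  if (any(params$residual_sd <= 0) || params$careless_sd <= 0) return(-Inf)
  N <- nrow(y)
  pii <- rep_len(params$person_prob, N)
  total <- 0
  for (i in seq_len(N)) {
    keep <- !is.na(y[i, ])
    if (!any(keep)) next
    mu <- params$intercept[keep] + params$loading[keep] * params$trait[i]
    la <- stats::dnorm(y[i, keep], mu, params$residual_sd[keep], log = TRUE)
    lc <- stats::dnorm(y[i, keep], params$careless_mean, params$careless_sd,
                       log = TRUE)
    hi <- pmax(log(pii[i]) + la, log1p(-pii[i]) + lc)
    total <- total + sum(hi + log(exp(log(pii[i]) + la - hi) +
                                  exp(log1p(-pii[i]) + lc - hi)))
  }
  total
}
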