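toy_params <- function(n_persons = 2, theta = c(0.5, -1), pii = c(0.9, 0.6)) {
  list(items = item_params(c(0.2, -0.4), c(1, 0.5), c(1L, -1L)),
       theta = theta, m = 2, n = 5, person_prob = pii,
       trait_sd = 1, trait_corr = NULL, attentive_prop = 0.8,
       concentration = 3)
}

test_that("marginal mixture likelihood collapses at degenerate weights", {
  set.seed(420)
  y <- matrix(runif(6, 0.05, 0.95), 3, 2)
  p <- toy_params(theta = c(0.5, -1, 0.2), pii = 1)
  pure_att <- sum(vapply(1:3, function(i)
    sum(beta_irm_log_density(y[i, ], p$theta[i], p$items)), numeric(1)))
  expect_equal(mixture_log_likelihood(y, p), pure_att)

  p$person_prob <- 0
  expect_equal(mixture_log_likelihood(y, p),
               sum(careless_log_density(y, 2, 5)))
})

test_that("mixture likelihood equals the brute-force two-branch sum per cell", {
  set.seed(421)
  y <- matrix(runif(6, 0.05, 0.95), 3, 2)
  p <- toy_params(theta = c(0.5, -1, 0.2), pii = c(0.9, 0.6, 0.3))
  brute <- 0
  for (i in 1:3) for (j in 1:2) {
    fa <- exp(beta_irm_log_density(y[i, j], p$theta[i], p$items[j, ]))
    fc <- dbeta(y[i, j], p$m, p$n)
    brute <- brute + log(p$person_prob[i] * fa + (1 - p$person_prob[i]) * fc)
  }
  expect_equal(mixture_log_likelihood(y, p), brute)

  # two-person, one-item toy against hand arithmetic
  y1 <- matrix(c(0.3, 0.7), 2, 1)
  ph <- list(items = item_params(0, 0), theta = c(0, 0), m = 1, n = 1,
             person_prob = c(0.5, 0.5))
  # both components uniform: every cell likelihood is exactly 1
  expect_equal(mixture_log_likelihood(y1, ph), 0)

  expect_error(mixture_log_likelihood(matrix(c(0, 0.5), 1), toy_params()),
               "strictly")
  # missing cells contribute nothing
  cell <- log(p$person_prob[2] *
                exp(beta_irm_log_density(y[2, 1], p$theta[2], p$items[1, ])) +
              (1 - p$person_prob[2]) * dbeta(y[2, 1], p$m, p$n))
  y[2, 1] <- NA
  expect_equal(mixture_log_likelihood(y, p), brute - cell)
})

test_that("log-prior matches closed forms and rejects out-of-support values", {
  pr <- prior_config()
  base <- toy_params()

  # flat Dirichlet(1,1): prior equal at any population proportion
  p1 <- base; p1$attentive_prop <- 0.3
  p2 <- base; p2$attentive_prop <- 0.7
  # only the hierarchical person-level term may differ; remove it to compare
  p1$person_prob <- p2$person_prob <- numeric(0)
  expect_equal(log_prior(p1, pr), log_prior(p2, pr))

  # the two-class Dirichlet reduces to a Beta density for pi_i
  p3 <- base; p3$person_prob <- 0.77
  p4 <- base; p4$person_prob <- 0.31
  om <- base$concentration; pp <- base$attentive_prop
  expect_equal(log_prior(p3, pr) - log_prior(p4, pr),
               dbeta(0.77, om * pp, om * (1 - pp), log = TRUE) -
               dbeta(0.31, om * pp, om * (1 - pp), log = TRUE))

  # support violations return -Inf, never raise
  neg_sd <- base; neg_sd$trait_sd <- -1
  expect_identical(log_prior(neg_sd, pr), -Inf)
  bad_m <- base; bad_m$m <- 0
  expect_identical(log_prior(bad_m, pr), -Inf)
  bad_pi <- base; bad_pi$attentive_prop <- 1
  expect_identical(log_prior(bad_pi, pr), -Inf)
  bad_corr <- toy_params()
  bad_corr$trait_sd <- c(1, 1)
  bad_corr$trait_corr <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_identical(log_prior(bad_corr, pr), -Inf)

  # finite on random in-support draws
  set.seed(422)
  for (k in 1:25) {
    p <- toy_params(pii = runif(2))
    p$m <- rexp(1) + 0.1; p$n <- rexp(1) + 0.1
    p$attentive_prop <- runif(1, 0.05, 0.95)
    p$concentration <- rexp(1) + 0.1
    expect_true(is.finite(log_prior(p, pr)))
  }
})

test_that("row-level Bayes rule matches hand computation", {
  # identical components and even prior: exactly one half
  p <- list(items = item_params(0, 0), theta = 0, m = 1, n = 1,
            person_prob = 0.5)
  expect_equal(posterior_class_probability(0.37, p), 0.5)

  p$person_prob <- 1
  expect_equal(posterior_class_probability(0.37, p), 1)

  # one-item toy: hand-computed Bayes rule
  p <- list(items = item_params(0.2, 1), theta = 0.5, m = 2, n = 5,
            person_prob = 0.8)
  y <- 0.6
  fa <- exp(beta_irm_log_density(y, 0.5, p$items))
  fc <- dbeta(y, 2, 5)
  expect_equal(posterior_class_probability(y, p),
               0.8 * fa / (0.8 * fa + 0.2 * fc))
  expect_error(posterior_class_probability(1, p), "strictly")
})

test_that("CFA mixture likelihood matches hand computation and its symmetries", {
  set.seed(423)
  y <- matrix(rnorm(6, 0.5, 0.2), 3, 2)
  p <- list(intercept = c(0.4, 0.6), loading = c(0.3, -0.2),
            residual_sd = c(0.1, 0.15), trait = c(0.5, -1, 0.2),
            careless_mean = 0.5, careless_sd = 0.3,
            person_prob = c(0.9, 0.7, 0.5))

  brute <- 0
  for (i in 1:3) for (j in 1:2) {
    fa <- dnorm(y[i, j], p$intercept[j] + p$loading[j] * p$trait[i],
                p$residual_sd[j])
    fc <- dnorm(y[i, j], 0.5, 0.3)
    brute <- brute + log(p$person_prob[i] * fa + (1 - p$person_prob[i]) * fc)
  }
  expect_equal(cfa_mixture_log_likelihood(y, p), brute)

  # degenerate mixture: ordinary one-factor CFA log-likelihood
  p1 <- p; p1$person_prob <- 1
  cfa_ll <- sum(vapply(1:3, function(i)
    sum(dnorm(y[i, ], p$intercept + p$loading * p$trait[i], p$residual_sd,
              log = TRUE)), numeric(1)))
  expect_equal(cfa_mixture_log_likelihood(y, p1), cfa_ll)

  # reflection symmetry: jointly flipping loadings and traits changes nothing
  p2 <- p; p2$loading <- -p$loading; p2$trait <- -p$trait
  expect_equal(cfa_mixture_log_likelihood(y, p2),
               cfa_mixture_log_likelihood(y, p))

  p3 <- p; p3$residual_sd <- c(0.1, -0.2)
  expect_identical(cfa_mixture_log_likelihood(y, p3), -Inf)
})
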