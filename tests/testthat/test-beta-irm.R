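test_that("shape parameters follow the acceptance/refusal closed form", {
  # all-zero parameters give the uniform Beta(1, 1)
  sp <- shape_params(0, item_params(0, 0))
  expect_equal(sp$accept, 1)
  expect_equal(sp$refuse, 1)

  # eta = 1: accept = e^{1/2}, refuse = e^{-1/2}, mean = logistic(1)
  sp <- shape_params(1, item_params(0, 0, wording = 1))
  expect_equal(sp$accept, exp(0.5))
  expect_equal(sp$refuse, exp(-0.5))
  expect_equal(sp$accept / (sp$accept + sp$refuse), plogis(1))

  # reverse-keyed item flips the trait effect
  expect_equal(expected_response(1, item_params(0, 0, wording = -1)),
               plogis(-1))

  # invalid inputs are rejected
  expect_error(item_params(NA, 0), "finite")
  expect_error(item_params(0, 0, wording = 0), "wording")
  expect_error(shape_params(c(0), item_params(0, 0, dimension = 2)),
               "dimension")
  expect_error(shape_params(NaN, item_params(0, 0)), "finite")
})

test_that("expected response is logistic, dispersion-free, and monotone", {
  theta_grid <- seq(-2.5, 2.5, by = 0.5)
  for (b in c(-1, 0, 1.3)) {
    lo <- vapply(theta_grid, expected_response, numeric(1),
                 items = item_params(b, 0))
    hi <- vapply(theta_grid, expected_response, numeric(1),
                 items = item_params(b, 3))
    expect_identical(lo, hi)            # bit-identical under dispersion change
    expect_equal(lo, plogis(theta_grid - b))
    expect_true(all(diff(lo) > 0))      # strictly increasing for wording +1
    neg <- vapply(theta_grid, expected_response, numeric(1),
                  items = item_params(b, 1, wording = -1))
    expect_true(all(diff(neg) < 0))
  }
  # eta = 0 gives the midpoint
  expect_equal(expected_response(2, item_params(2, 1)), 0.5)
})

test_that("log-density matches closed-form Beta cases and normalizes", {
  # Beta(1,1): flat density, log 0 everywhere
  expect_equal(beta_irm_log_density(0.5, 0, item_params(0, 0)), 0)
  expect_equal(beta_irm_log_density(0.123, 0, item_params(0, 0)), 0)

  # eta = 0 with dispersion 2*log(2) gives Beta(2,2); density 1.5 at midpoint
  it <- item_params(0, 2 * log(2))
  expect_equal(shape_params(0, it)$accept, 2)
  expect_equal(beta_irm_log_density(0.5, 0, it), log(1.5))

  expect_error(beta_irm_log_density(0, 0, item_params(0, 0)), "strictly")
  expect_error(beta_irm_log_density(1, 0, item_params(0, 0)), "strictly")

  # numerical normalization over 100 random parameter draws
  set.seed(401)
  for (k in 1:100) {
    it <- item_params(rnorm(1), runif(1, 0, 3), sample(c(-1, 1), 1))
    expect_equal(density_mass(rnorm(1), it), 1, tolerance = 1e-6)
  }
})

test_that("conditional variance is the Beta moment and decreases in dispersion", {
  # uniform case: 1/12
  expect_equal(conditional_variance(0, item_params(0, 0)), 1 / 12)

  # strictly decreasing in dispersion over a grid of eta values
  for (eta in c(-2, -0.5, 0, 1, 2.5)) {
    v <- vapply(seq(0, 3, by = 0.25), function(a)
      conditional_variance(eta, item_params(0, a)), numeric(1))
    expect_true(all(diff(v) < 0))
  }

  # Monte-Carlo oracle at one parameter point
  set.seed(402)
  it <- item_params(0.4, 1.2)
  sp <- shape_params(0.8, it)
  draws <- rbeta(1e5, sp$accept, sp$refuse)
  expect_equal(conditional_variance(0.8, it), var(draws), tolerance = 0.02)
})

test_that("numerical item information behaves like Fisher information", {
  grid <- seq(-3, 3, by = 0.25)
  info_lo <- item_information(grid, item_params(0, 0.5))
  info_hi <- item_information(grid, item_params(0, 2.5))
  expect_true(all(info_lo >= -1e-8))
  expect_true(all(info_hi >= -1e-8))
  # higher dispersion concentrates the response density: more information
  expect_gt(max(info_hi), max(info_lo))

  # Monte-Carlo oracle: information = E[(d/dtheta log f)^2] at one point
  set.seed(403)
  it <- item_params(0.3, 1)
  th <- 0.5; h <- 1e-4
  sp <- shape_params(th, it)
  ys <- rbeta(2e5, sp$accept, sp$refuse)
  score <- (dbeta(ys, shape_params(th + h, it)$accept,
                  shape_params(th + h, it)$refuse, log = TRUE) -
            dbeta(ys, shape_params(th - h, it)$accept,
                  shape_params(th - h, it)$refuse, log = TRUE)) / (2 * h)
  expect_equal(item_information(th, it), mean(score^2), tolerance = 0.05)

  expect_error(item_information(numeric(0), item_params(0, 0)), "grid")
})
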