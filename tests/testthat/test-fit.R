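small_sim <- function(seed = 428, n = 40, j = 6, prop = 0.2) {
  simulate_vas(n_persons = n, n_items = j, n_negative = j %/% 2,
               prop_careless = prop, seed = seed)
}

test_that("identical data, seed and spec give identical draws", {
  sim <- small_sim()
  f1 <- vasmix(sim$responses, sim$items, chains = 2, iter = 240, seed = 5)
  f2 <- vasmix(sim$responses, sim$items, chains = 2, iter = 240, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$point, f2$point)

  f3 <- vasmix(sim$responses, sim$items, chains = 2, iter = 240, seed = 6)
  expect_false(identical(f1$point, f3$point))
})

test_that("fit objects expose coherent posterior summaries", {
  sim <- small_sim()
  fit <- vasmix(sim$responses, sim$items, chains = 2, iter = 300, seed = 9)
  expect_s3_class(fit, "vasmix_fit")
  expect_length(fit$person_prob, 40)
  expect_true(all(fit$person_prob > 0 & fit$person_prob < 1))
  expect_true(all(fit$ci95[, 1] <= fit$point & fit$point <= fit$ci95[, 2]))
  expect_true(all(is.finite(fit$epsr)))
  expect_equal(nrow(fit$theta), 40)

  bfit <- vasmix(sim$responses, sim$items, model = "beta_irm",
                 chains = 2, iter = 300, seed = 9)
  expect_identical(bfit$person_prob, rep(1, 40))
  expect_false(any(grepl("^(m|n|pi|omega)$", names(bfit$point))))

  # methods run and return sensibly shaped objects
  expect_output(print(fit), "Beta mixture IRM")
  expect_s3_class(summary(fit), "summary.vasmix_fit")
  expect_true(all(c("m", "n", "pi") %in% names(coef(fit))))
  r <- residuals(fit)
  expect_equal(dim(r), dim(sim$responses))
  y_rep <- simulate(fit, nsim = 2, seed = 1)
  expect_length(y_rep, 2)
  expect_true(all(y_rep[[1]] > 0 & y_rep[[1]] < 1))
})

test_that("input validation catches malformed calls", {
  sim <- small_sim()
  bad <- sim$responses; bad[1, 1] <- 1.4
  expect_error(vasmix(bad), "0, 1")
  expect_error(vasmix(sim$responses, sim$items, iter = 100, burnin = 100),
               "MCMC")
  two_dim <- data.frame(wording = rep(1L, 6), dimension = rep(1:2, 3))
  expect_error(vasmix(sim$responses, two_dim, model = "cfa_mixture"),
               "unidimensional")
  expect_error(vasmix(sim$responses, data.frame(wording = rep(1L, 3))),
               "rows")
})

test_that("two-dimensional fits estimate a trait correlation", {
  set.seed(440)
  n <- 80; j <- 8
  items <- item_params(difficulty = rnorm(j), dispersion = runif(j, 0.5, 2),
                       wording = rep(c(1L, -1L), 4),
                       dimension = rep(1:2, each = 4))
  rho <- 0.6
  th <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  y <- matrix(NA_real_, n, j)
  for (i in seq_len(n)) {
    sp <- shape_params(th[i, ], items)
    y[i, ] <- rbeta(j, sp$accept, sp$refuse)
  }
  y <- pmin(pmax(y, 1e-3), 1 - 1e-3)

  fit <- vasmix(y, items, model = "mixture", chains = 2, iter = 600,
                seed = 440)
  expect_true("R[1,2]" %in% names(fit$point))
  expect_true(all(c("sigma[1]", "sigma[2]") %in% names(fit$point)))
  r12 <- fit$point[["R[1,2]"]]
  expect_true(r12 > -1 && r12 < 1)
  # positively correlated generating traits show up as a positive estimate
  expect_gt(r12, 0)
  expect_equal(ncol(fit$theta), 2)
  # per-dimension traits track their own generating dimension
  expect_gt(recovery_correlation(fit$theta[, 1], th[, 1]), 0.5)
  expect_gt(recovery_correlation(fit$theta[, 2], th[, 2]), 0.5)
})

test_that("the mixture model recovers its own generating parameters", {
  sim <- simulate_vas(prop_careless = 0.25, pattern = "beta_extremes",
                      seed = 429)
  fit <- vasmix(sim$responses, sim$items, chains = 2, iter = 1500, seed = 429)

  b_hat <- fit$point[sprintf("b[%d]", 1:10)]
  a_hat <- fit$point[sprintf("alpha[%d]", 1:10)]
  expect_gt(recovery_correlation(b_hat, sim$items$difficulty), 0.9)
  expect_gt(recovery_correlation(a_hat, sim$items$dispersion), 0.9)

  # careless proportion recovered within +-0.08 in the model-true condition
  expect_lt(abs((1 - fit$point[["pi"]]) - 0.25), 0.08)
  # careless shapes near the generating Beta(0.5, 0.5)
  expect_lt(abs(fit$point[["m"]] - 0.5), 0.4)
  expect_lt(abs(fit$point[["n"]] - 0.5), 0.4)

  # attentive persons' traits track the truth
  att <- sim$membership == "attentive"
  expect_gt(recovery_correlation(fit$theta[att, 1], sim$traits[att]), 0.9)

  # the attentive component does not absorb the careless rows:
  # careless persons receive clearly lower attentiveness probabilities
  expect_gt(mean(fit$person_prob[att]) - mean(fit$person_prob[!att]), 0.3)
})

test_that("the plain Beta IRM recovers traits on purely attentive data", {
  sim <- simulate_vas(n_persons = 200, prop_careless = 0, seed = 430)
  fit <- vasmix(sim$responses, sim$items, model = "beta_irm",
                chains = 2, iter = 800, seed = 430)
  expect_gt(recovery_correlation(fit$theta[, 1], sim$traits), 0.9)
  expect_gt(recovery_correlation(fit$point[sprintf("b[%d]", 1:10)],
                                 sim$items$difficulty), 0.9)
})

test_that("the CFA mixture recovers sign-constrained loadings on model-true data", {
  set.seed(431)
  n <- 150; j <- 8
  wording <- rep(c(-1L, 1L), each = 4)
  lambda <- wording * runif(j, 0.08, 0.25)
  nu <- runif(j, 0.3, 0.7)
  sdj <- runif(j, 0.05, 0.15)
  theta <- rnorm(n)
  y <- sapply(seq_len(j), function(jj) nu[jj] + lambda[jj] * theta +
                rnorm(n, 0, sdj[jj]))
  careless <- sample(n, 30)
  y[careless, ] <- matrix(rnorm(30 * j, 0.5, 0.3), 30, j)
  y <- pmin(pmax(y, 0.001), 0.999)

  fit <- vasmix(y, data.frame(wording = wording), model = "cfa_mixture",
                chains = 2, iter = 800, seed = 431)
  lam_hat <- fit$point[sprintf("lambda[%d]", 1:j)]
  expect_true(all(sign(lam_hat) == wording))
  expect_gt(recovery_correlation(abs(lam_hat), abs(lambda)), 0.8)

  # on its own model the normal mixture classifies adequately
  truth <- ifelse(seq_len(n) %in% careless, "careless", "attentive")
  acc <- confusion_metrics(truth, classify(fit, "proportion"))$accuracy
  expect_gt(acc, 0.8)
})
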