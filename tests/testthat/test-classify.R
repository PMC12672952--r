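test_that("threshold rule labels by strict comparison at 0.5", {
  cl <- classify_threshold(c(0.9, 0.4))
  expect_equal(as.character(cl$labels), c("attentive", "careless"))
  # boundary probability counts as attentive (careless is strictly below)
  expect_equal(as.character(classify_threshold(0.5)$labels), "attentive")
  expect_equal(sum(classify_threshold(c(0.6, 0.7, 0.51))$labels == "careless"),
               0L)
  expect_error(classify_threshold(c(0.5, 1.2)), "0, 1")
})

test_that("proportion rule flags exactly k lowest-probability persons", {
  cl <- classify_proportion(seq(0.05, 0.95, length.out = 10), 0.8)
  expect_equal(cl$flagged_count, 2L)
  expect_equal(sum(cl$labels == "careless"), 2L)
  expect_equal(which(cl$labels == "careless"), c(1L, 2L))

  expect_equal(sum(classify_proportion(runif(10), 1)$labels == "careless"), 0L)

  # ties broken by ascending person index
  cl <- classify_proportion(c(0.1, 0.1, 0.9, 0.8, 0.7), 0.8)
  expect_equal(cl$flagged_count, 1L)
  expect_equal(which(cl$labels == "careless"), 1L)

  # k always matches round(N * (1 - pi-hat)), half away from zero
  set.seed(418)
  for (rep in 1:25) {
    n <- sample(5:40, 1); p <- runif(1, 0.5, 0.99)
    cl <- classify_proportion(runif(n), p)
    expect_equal(sum(cl$labels == "careless"), floor(n * (1 - p) + 0.5))
  }
  expect_error(classify_proportion(runif(5), 0), "attentive_prop")
})

test_that("confusion metrics use the attentive-oriented study definitions", {
  m <- confusion_metrics(c("attentive", "attentive", "attentive", "careless"),
                         c("attentive", "attentive", "careless", "attentive"))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$fpr, 1)       # the one careless person was labeled attentive
  expect_equal(m$fnr, 1 / 3)

  truth <- c("attentive", "careless", "attentive")
  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)

  # degenerate all-attentive predictor: perfect sensitivity, total FPR
  all_att <- confusion_metrics(c("attentive", "careless", "careless"),
                               rep("attentive", 3))
  expect_equal(all_att$sensitivity, 1)
  expect_equal(all_att$fpr, 1)

  # zero denominators give NA, never 0
  no_careless <- confusion_metrics(rep("attentive", 3), rep("attentive", 3))
  expect_true(is.na(no_careless$fpr))
  all_careless_pred <- confusion_metrics(c("attentive", "careless"),
                                         rep("careless", 2))
  expect_true(is.na(all_careless_pred$precision))

  expect_error(confusion_metrics(character(0), character(0)), "empty")
  expect_error(confusion_metrics("attentive", c("attentive", "careless")),
               "length")
  expect_error(confusion_metrics("attentive", "bored"), "labels")
})

test_that("fnr is the complement of sensitivity and metrics are permutation-equivariant", {
  set.seed(419)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    truth <- sample(c("attentive", "careless"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
    pred <- sample(c("attentive", "careless"), n, replace = TRUE)
    if (!any(truth == "attentive")) next
    m <- confusion_metrics(truth, pred)
    expect_equal(m$fnr, 1 - m$sensitivity)
    perm <- sample(n)
    expect_equal(confusion_metrics(truth[perm], pred[perm]), m)
  }
})

test_that("classify() dispatches both rules on a fitted object", {
  fake <- structure(list(model = "mixture",
                         person_prob = c(0.95, 0.2, 0.9, 0.85),
                         point = c(pi = 0.75)),
                    class = "vasmix_fit")
  expect_equal(sum(classify(fake, "threshold")$labels == "careless"), 1L)
  expect_equal(classify(fake, "proportion")$flagged_count, 1L)
  fake$model <- "beta_irm"
  expect_error(classify(fake), "does not classify")
})
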