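class_levels <- c("attentive", "careless")

new_classification <- function(labels, rule, extra) {
  structure(c(list(labels = factor(labels, levels = class_levels),
                   rule = rule), extra),
            class = "vasmix_class")
}

#' Threshold rule for careless classification
#'
#' Flags a respondent as careless when the posterior attentiveness
#' probability falls strictly below the threshold (default 0.5, i.e. the
#' probability of attentiveness is lower than the probability of
#' carelessness).  A probability exactly at the threshold is labelled
#' attentive.  Under low contamination the hierarchical prior pulls
#' individual probabilities toward attentiveness, so this rule can fail to
#' flag anyone; see [classify_proportion] for the recommended alternative.
#'
#' @param person_prob numeric vector of attentiveness probabilities in
#'   \[0, 1\] (typically `fit$person_prob`).
#' @param threshold classification threshold.
#' @return a `vasmix_class` object with per-person labels.
#' @export
classify_threshold <- function(person_prob, threshold = 0.5) {
  if (any(person_prob < 0 | person_prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  labels <- ifelse(person_prob < threshold, "careless", "attentive")
  new_classification(labels, "threshold", list(threshold = threshold,
                                               person_prob = person_prob))
}

#' Proportion (ranking) rule for careless classification
#'
#' Uses the estimated population attentive proportion: flags the
#' `k = round(N * (1 - attentive_prop))` respondents with the smallest
#' attentiveness probabilities as careless (ties broken by ascending person
#' index; rounding is half-away-from-zero).  The count is anchored by the
#' population-level estimate, which controls the false positive rate far
#' better than the fixed 0.5 threshold when contamination is low.
#'
#' @param person_prob numeric vector of attentiveness probabilities.
#' @param attentive_prop estimated population attentive proportion in (0, 1\];
#'   typically the posterior mean of `pi`.
#' @return a `vasmix_class` object with per-person labels and the flagged
#'   count.
#' @export
classify_proportion <- function(person_prob, attentive_prop) {
  if (attentive_prop <= 0 || attentive_prop > 1)
    stop("attentive_prop must lie in (0, 1]", call. = FALSE)
  N <- length(person_prob)
  k <- round_half_up(N * (1 - attentive_prop))
  labels <- rep("attentive", N)
  if (k > 0L) {
    ord <- order(person_prob, seq_len(N))  # ties: ascending person index
    labels[ord[seq_len(k)]] <- "careless"
  }
  new_classification(labels, "proportion",
                     list(flagged_count = as.integer(k),
                          attentive_prop = attentive_prop,
                          person_prob = person_prob))
}

#' Classify respondents from a fitted mixture model
#'
#' Convenience wrapper applying either classification rule to a fitted
#' `vasmix_fit`.
#'
#' @param fit a `vasmix_fit` from a mixture model.
#' @param rule `"threshold"` or `"proportion"`.
#' @param threshold threshold for the threshold rule.
#' @return a `vasmix_class` object.
#' @export
classify <- function(fit, rule = c("threshold", "proportion"),
                     threshold = 0.5) {
  rule <- match.arg(rule)
  if (fit$model == "beta_irm")
    stop("the attentive-only Beta IRM does not classify respondents",
         call. = FALSE)
  if (rule == "threshold") classify_threshold(fit$person_prob, threshold)
  else classify_proportion(fit$person_prob, fit$point[["pi"]])
}

#' @export
print.vasmix_class <- function(x, ...) {
  cat("Careless classification (", x$rule, " rule): ",
      sum(x$labels == "careless"), " of ", length(x$labels),
      " flagged careless\n", sep = "")
  invisible(x)
}

#' Confusion-matrix metrics for careless classification
#'
#' Scores predicted labels against known truth with the five study metrics.
#' Note the field-specific orientation: sensitivity, precision and FNR are
#' defined with respect to the *attentive* class, and the false positive rate
#' is the proportion of truly careless respondents incorrectly labelled
#' attentive (a careless respondent slipping through is the costly error).
#' Ratios with a zero denominator are reported as `NA`, never as 0.
#'
#' @param truth true labels (`"attentive"`/`"careless"`, factor or character,
#'   e.g. `sim$membership`).
#' @param predicted predicted labels of the same length (or a `vasmix_class`).
#' @return a one-row `data.frame` with columns `accuracy`, `sensitivity`,
#'   `precision`, `fpr`, `fnr`.
#' @examples
#' confusion_metrics(c("attentive", "attentive", "careless"),
#'                   c("attentive", "careless", "careless"))
#' @export
confusion_metrics <- function(truth, predicted) {
  if (inherits(predicted, "vasmix_class")) predicted <- predicted$labels
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  if (!all(c(truth, predicted) %in% class_levels))
    stop("labels must be 'attentive' or 'careless'", call. = FALSE)

  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  true_att <- truth == "attentive"
  pred_att <- predicted == "attentive"
  data.frame(
    accuracy = mean(truth == predicted),
    sensitivity = ratio(sum(true_att & pred_att), sum(true_att)),
    precision = ratio(sum(true_att & pred_att), sum(pred_att)),
    fpr = ratio(sum(!true_att & pred_att), sum(!true_att)),
    fnr = ratio(sum(true_att & !pred_att), sum(true_att)))
}
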