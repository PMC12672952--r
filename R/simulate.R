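round_half_up <- function(x) floor(x + 0.5)

#' Draw generating parameters for a simulated study dataset
#'
#' Item difficulties and person traits are standard normal, item dispersions
#' are uniform on \[0, 3\], and the first `n_negative` items are negatively
#' worded.  The generating measurement model is unidimensional, which is the
#' hardest case for careless-respondent detection (multidimensional scales
#' leave more structure to distinguish attentive patterns).
#'
#' @param n_persons number of respondents.
#' @param n_items number of items.
#' @param n_negative number of negatively worded items (placed first).
#' @param seed optional integer RNG seed.
#' @return a list with elements `items` (an [item_params] table) and `traits`
#'   (numeric vector of length `n_persons`).
#' @export
draw_generating_params <- function(n_persons = 300L, n_items = 10L,
                                   n_negative = 5L, seed = NULL) {
  if (n_negative > n_items)
    stop("n_negative cannot exceed n_items", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  items <- item_params(
    difficulty = stats::rnorm(n_items),
    dispersion = stats::runif(n_items, 0, 3),
    wording = rep(c(-1L, 1L), c(n_negative, n_items - n_negative)),
    dimension = 1L)
  list(items = items, traits = stats::rnorm(n_persons))
}

#' Simulate a contaminated VAS response matrix
#'
#' Generates a person-by-item response matrix following the simulation design:
#' attentive rows follow the Beta IRM with parameters from
#' [draw_generating_params]; a fixed number `round(n_persons * prop_careless)`
#' of rows, chosen uniformly without replacement, are replaced by careless
#' responses drawn under the requested pattern.  The fixed careless count (as
#' opposed to per-person Bernoulli contamination) gives classification metrics
#' a deterministic denominator within each dataset.  All responses are
#' squeezed into `[clamp, 1 - clamp]`.
#'
#' @param n_persons sample size (default 300).
#' @param n_items number of items (default 10).
#' @param n_negative number of negatively worded items (default 5, placed
#'   first).
#' @param pattern careless generating pattern, a [careless_pattern] or its
#'   name.
#' @param prop_careless proportion of careless respondents in \[0, 1).
#' @param seed optional integer RNG seed; identical seeds give byte-identical
#'   datasets.
#' @param clamp boundary squeeze constant.
#' @return an object of class `vas_sim`: a list with `responses` (matrix),
#'   `items`, `traits`, `membership` (factor with levels `attentive`,
#'   `careless`) and `condition` (the generating settings).
#' @examples
#' sim <- simulate_vas(n_persons = 50, prop_careless = 0.1, seed = 1)
#' table(sim$membership)
#' @export
simulate_vas <- function(n_persons = 300L, n_items = 10L, n_negative = 5L,
                         pattern = "beta_extremes", prop_careless = 0.25,
                         seed = NULL, clamp = CLAMP) {
  if (prop_careless < 0 || prop_careless >= 1)
    stop("prop_careless must lie in [0, 1)", call. = FALSE)
  pattern <- as_careless_pattern(pattern)
  if (!is.null(seed)) set.seed(seed)

  gen <- draw_generating_params(n_persons, n_items, n_negative)
  items <- gen$items
  traits <- gen$traits

  eta <- tcrossprod(traits, items$wording)              # N x J
  eta <- sweep(eta, 2, items$difficulty)
  accept <- exp(sweep(eta, 2, items$dispersion, "+") / 2)
  refuse <- exp(-sweep(eta, 2, items$dispersion, "-") / 2)
  y <- matrix(stats::rbeta(n_persons * n_items, accept, refuse),
              n_persons, n_items,
              dimnames = list(paste0("p", seq_len(n_persons)),
                              paste0("item", seq_len(n_items))))

  n_careless <- round_half_up(n_persons * prop_careless)
  membership <- rep("attentive", n_persons)
  if (n_careless > 0L) {
    idx <- sample(n_persons, n_careless)
    membership[idx] <- "careless"
    y[idx, ] <- sample_careless(pattern, n_careless, n_items, clamp = clamp)
  }
  y <- clamp_unit(y, clamp)

  structure(list(
    responses = y,
    items = items,
    traits = traits,
    membership = factor(membership, levels = c("attentive", "careless")),
    condition = list(n_persons = n_persons, n_items = n_items,
                     n_negative = n_negative, pattern = pattern,
                     prop_careless = prop_careless, seed = seed,
                     clamp = clamp)),
    class = "vas_sim")
}

#' @export
print.vas_sim <- function(x, ...) {
  cond <- x$condition
  cat("Simulated VAS dataset:", cond$n_persons, "persons x", cond$n_items,
      "items\n")
  cat("  careless pattern:", cond$pattern$kind,
      sprintf("(proportion %.2f, %d rows)", cond$prop_careless,
              sum(x$membership == "careless")), "\n")
  invisible(x)
}
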