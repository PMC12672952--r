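#' Item parameter table for the Beta item response model
#'
#' Constructs and validates the per-item parameter table used throughout the
#' package: item difficulty on the latent-trait scale, item dispersion on the
#' log-precision scale, the wording sign (+1 for positively worded items, -1
#' for reverse-keyed items) and the latent dimension each item measures
#' (simple structure: one dimension per item).
#'
#' @param difficulty numeric vector of item difficulties (trait scale).
#' @param dispersion numeric vector of item dispersions; higher values give a
#'   more peaked conditional response density (lower variance) at fixed trait.
#' @param wording integer vector in \{-1, +1\}; recycled if length 1.
#' @param dimension positive integer index of the latent dimension measured by
#'   each item; recycled if length 1.
#' @return a `data.frame` of class `item_params` with one row per item.
#' @examples
#' item_params(difficulty = c(-1, 0, 1), dispersion = 1, wording = c(1, 1, -1))
#' @export
item_params <- function(difficulty, dispersion, wording = 1L, dimension = 1L) {
  n <- length(difficulty)
  dispersion <- rep_len(dispersion, n)
  wording <- rep_len(as.integer(wording), n)
  dimension <- rep_len(as.integer(dimension), n)
  if (!all(is.finite(difficulty)) || !all(is.finite(dispersion)))
    stop("item difficulties and dispersions must be finite", call. = FALSE)
  if (!all(wording %in% c(-1L, 1L)))
    stop("item wording must be exactly -1 or +1", call. = FALSE)
  if (any(dimension < 1L))
    stop("dimension indices must be positive integers", call. = FALSE)
  out <- data.frame(difficulty = as.numeric(difficulty),
                    dispersion = as.numeric(dispersion),
                    wording = wording, dimension = dimension)
  class(out) <- c("item_params", "data.frame")
  out
}

as_item_params <- function(x) {
  if (inherits(x, "item_params")) return(x)
  if (is.data.frame(x)) {
    need <- c("difficulty", "dispersion", "wording")
    if (!all(need %in% names(x)))
      stop("item table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    dimension <- if ("dimension" %in% names(x)) x$dimension else 1L
    return(item_params(x$difficulty, x$dispersion, x$wording, dimension))
  }
  stop("cannot interpret `items` as an item parameter table", call. = FALSE)
}

check_theta <- function(theta, items) {
  theta <- as.numeric(theta)
  if (!all(is.finite(theta)))
    stop("latent trait vector must be finite", call. = FALSE)
  if (max(items$dimension) > length(theta))
    stop("trait vector shorter than the largest item dimension index",
         call. = FALSE)
  theta
}

# linear predictor eta_j = s_j * theta[d(j)] - b_j, one value per item
linear_predictor <- function(theta, items) {
  items$wording * theta[items$dimension] - items$difficulty
}

#' Beta IRM shape parameters
#'
#' Maps a latent trait vector and item parameters to the two shape parameters
#' of the conditional Beta response distribution.  With linear predictor
#' `eta = wording * theta[dimension] - difficulty`, the "acceptance" shape
#' (pull toward the high end of the scale) is `exp((eta + dispersion)/2)` and
#' the "refusal" shape (pull toward the low end) is `exp(-(eta - dispersion)/2)`.
#' The implied mean `accept/(accept + refuse)` is `plogis(eta)` and does not
#' depend on the dispersion, which only shifts the total concentration
#' `accept + refuse`.
#'
#' @param theta numeric trait vector, one entry per latent dimension.
#' @param items an [item_params] table (or coercible data frame).
#' @return a `data.frame` with columns `accept` and `refuse`, one row per item.
#' @examples
#' it <- item_params(0, 0)
#' shape_params(0, it) # Beta(1, 1): the uniform distribution
#' @export
shape_params <- function(theta, items) {
  items <- as_item_params(items)
  theta <- check_theta(theta, items)
  eta <- linear_predictor(theta, items)
  data.frame(accept = exp((eta + items$dispersion) / 2),
             refuse = exp(-(eta - items$dispersion) / 2))
}

#' Expected response under the Beta IRM
#'
#' The expected response of an attentive respondent is the logistic function
#' of the linear predictor, `plogis(wording * theta[dimension] - difficulty)`,
#' the familiar S-shaped item characteristic curve.  It is invariant to the
#' item dispersion parameter.
#'
#' @inheritParams shape_params
#' @return numeric vector of expected responses in (0, 1), one per item.
#' @export
expected_response <- function(theta, items) {
  items <- as_item_params(items)
  theta <- check_theta(theta, items)
  stats::plogis(linear_predictor(theta, items))
}

#' Log-density of an attentive response
#'
#' Evaluates the log of the conditional Beta density of a response `y` in the
#' open unit interval, given the latent trait and item parameters.
#'
#' @param y numeric vector of responses, strictly inside (0, 1); recycled
#'   against the items.
#' @inheritParams shape_params
#' @return numeric vector of log-densities.
#' @export
beta_irm_log_density <- function(y, theta, items) {
  items <- as_item_params(items)
  if (any(y <= 0 | y >= 1))
    stop("responses must lie strictly inside (0, 1); clamp boundary values first",
         call. = FALSE)
  sp <- shape_params(theta, items)
  stats::dbeta(y, sp$accept, sp$refuse, log = TRUE)
}

#' Conditional response variance under the Beta IRM
#'
#' The variance of the conditional Beta response distribution,
#' `mu * (1 - mu) / (accept + refuse + 1)`.  Strictly decreasing in the item
#' dispersion at fixed trait and difficulty.
#'
#' @inheritParams shape_params
#' @return numeric vector of conditional variances, one per item.
#' @export
conditional_variance <- function(theta, items) {
  items <- as_item_params(items)
  sp <- shape_params(theta, items)
  mu <- sp$accept / (sp$accept + sp$refuse)
  mu * (1 - mu) / (sp$accept + sp$refuse + 1)
}

#' Numerical item information function
#'
#' Fisher information of a single item across a grid of trait values, computed
#' numerically: the expectation over the response (201-point Gauss-Legendre
#' quadrature on (0, 1) by default) of the negative second derivative of the
#' log-density with respect to the trait (central differences, step 1e-4).
#' More dispersed (higher-precision) items carry a more peaked information
#' function.
#'
#' @param theta_grid numeric vector of trait values at which to evaluate the
#'   information.
#' @param item a one-row [item_params] table.
#' @param n_quad number of Gauss-Legendre quadrature nodes on (0, 1).
#' @param step central-difference step in the trait.
#' @return numeric vector of information values (nonnegative up to numerical
#'   error), one per grid point.
#' @export
item_information <- function(theta_grid, item, n_quad = 201L, step = 1e-4) {
  item <- as_item_params(item)
  if (nrow(item) != 1L)
    stop("item_information expects a single item", call. = FALSE)
  theta_grid <- as.numeric(theta_grid)
  if (length(theta_grid) < 1L || !all(is.finite(theta_grid)))
    stop("degenerate trait grid", call. = FALSE)
  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  d <- item$dimension
  lf <- function(th) {
    tv <- numeric(d); tv[d] <- th
    beta_irm_log_density(gl$x, tv, item)
  }
  vapply(theta_grid, function(th) {
    f0 <- lf(th)
    d2 <- (lf(th + step) - 2 * f0 + lf(th - step)) / step^2
    -sum(gl$w * exp(f0) * d2)
  }, numeric(1))
}
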