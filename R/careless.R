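#' Log-density of the careless response component
#'
#' The careless class is modelled as a single Beta(m, n) distribution shared
#' across all persons and items: careless respondents do not process item
#' content, so their responses carry no trait or item structure.  The common
#' Beta acts as a residual class absorbing the marginal distribution of
#' whatever careless behaviours are present.
#'
#' @param y numeric vector of responses strictly inside (0, 1).
#' @param m,n positive shape parameters (pull toward 1 and 0 respectively).
#' @return numeric vector of log-densities.
#' @export
careless_log_density <- function(y, m, n) {
  if (m <= 0 || n <= 0)
    stop("careless shape parameters must be strictly positive", call. = FALSE)
  if (any(y <= 0 | y >= 1))
    stop("responses must lie strictly inside (0, 1)", call. = FALSE)
  stats::dbeta(y, m, n, log = TRUE)
}

#' Careless response generating patterns
#'
#' The three careless behaviours used in the simulation study:
#' \describe{
#'   \item{`beta_extremes`}{random responses clustered at both ends of the
#'     scale, i.i.d. Beta(0.5, 0.5).}
#'   \item{`end_preference`}{overly consistent responding: each person is
#'     first assigned to prefer the left or right end with probability 1/2,
#'     then all of that person's responses are drawn uniformly from (0, 0.2)
#'     or (0.8, 1) respectively, regardless of item wording.}
#'   \item{`midpoint_normal`}{random responses clustered at the midpoint,
#'     drawn from a normal with mean 0.5 and SD 0.25 truncated to (0, 1).}
#' }
#' Only the first pattern is itself Beta-distributed; the other two can only
#' be approximated by the model's careless component, which is the point of
#' including them.  Pattern parameters default to the study values but may be
#' overridden for extensions.
#'
#' @param kind one of `"beta_extremes"`, `"end_preference"`,
#'   `"midpoint_normal"`.
#' @param ... optional overrides of the pattern parameters (`shape1`,
#'   `shape2` for `beta_extremes`; `low`, `high`, `p_left` for
#'   `end_preference`; `mean`, `sd` for `midpoint_normal`).
#' @return an object of class `careless_pattern`.
#' @export
careless_pattern <- function(kind = c("beta_extremes", "end_preference",
                                      "midpoint_normal"), ...) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    beta_extremes   = list(shape1 = 0.5, shape2 = 0.5),
    end_preference  = list(low = c(0, 0.2), high = c(0.8, 1), p_left = 0.5),
    midpoint_normal = list(mean = 0.5, sd = 0.25))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(pars))
    if (length(bad))
      stop("unknown parameters for pattern '", kind, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    pars[names(dots)] <- dots
  }
  structure(c(list(kind = kind), pars), class = "careless_pattern")
}

as_careless_pattern <- function(x) {
  if (inherits(x, "careless_pattern")) return(x)
  if (is.character(x) && length(x) == 1L) return(careless_pattern(x))
  stop("unknown careless pattern", call. = FALSE)
}

# boundary squeeze shared by all generators: Beta log-densities must stay finite
CLAMP <- 1e-3

clamp_unit <- function(y, clamp = CLAMP) pmin(pmax(y, clamp), 1 - clamp)

#' Sample careless responses
#'
#' Draws a person-by-item block of careless responses under one of the three
#' generating patterns (see [careless_pattern]).  For `end_preference` the
#' preferred side is a person-level attribute: all responses within a row fall
#' on the same side of the scale.  All draws are squeezed into
#' `[clamp, 1 - clamp]` so that Beta log-densities evaluated on them are
#' finite.
#'
#' @param pattern a [careless_pattern] or its name.
#' @param n_persons number of careless respondents (rows).
#' @param n_items number of items (columns).
#' @param seed optional integer; if supplied, sets the RNG seed first.
#' @param clamp boundary squeeze constant (default 1e-3).
#' @return an `n_persons` by `n_items` numeric matrix with entries strictly
#'   inside (0, 1).
#' @export
sample_careless <- function(pattern, n_persons, n_items = 1L, seed = NULL,
                            clamp = CLAMP) {
  pattern <- as_careless_pattern(pattern)
  if (n_persons < 1L) stop("n_persons must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_persons * n_items
  y <- switch(pattern$kind,
    beta_extremes = matrix(stats::rbeta(n, pattern$shape1, pattern$shape2),
                           n_persons, n_items),
    end_preference = {
      left <- stats::runif(n_persons) < pattern$p_left
      lo <- ifelse(left, pattern$low[1], pattern$high[1])
      hi <- ifelse(left, pattern$low[2], pattern$high[2])
      matrix(stats::runif(n, rep(lo, n_items), rep(hi, n_items)),
             n_persons, n_items)
    },
    midpoint_normal = {
      # inverse-cdf draw from the truncated normal on (0, 1)
      plo <- stats::pnorm(0, pattern$mean, pattern$sd)
      phi <- stats::pnorm(1, pattern$mean, pattern$sd)
      u <- stats::runif(n, plo, phi)
      matrix(stats::qnorm(u, pattern$mean, pattern$sd), n_persons, n_items)
    })
  clamp_unit(y, clamp)
}
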