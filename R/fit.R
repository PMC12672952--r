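#' Prior configuration for the Beta mixture IRM
#'
#' Collects the hyperparameters of the diffuse prior stack: normal priors on
#' item difficulty and dispersion, half-Cauchy priors on trait standard
#' deviations, on the careless Beta shapes and on the Dirichlet concentration,
#' an LKJ prior on the trait correlation matrix (unused in unidimensional
#' fits), a hierarchical Dirichlet prior on the per-person attentiveness
#' probabilities, and a flat Dirichlet(1, 1) prior on the population attentive
#' proportion.
#'
#' @param item_prior_sd normal prior SD for item difficulties and dispersions.
#' @param trait_sd_scale half-Cauchy scale for each trait SD.
#' @param lkj_shape LKJ shape for the trait correlation matrix.
#' @param careless_shape_scale half-Cauchy scale for the careless Beta shapes
#'   m and n.
#' @param dirichlet_base base Dirichlet parameters for the population
#'   attentive proportion (default `c(1, 1)`: uniform).
#' @param concentration_scale half-Cauchy scale for the Dirichlet
#'   concentration.
#' @return a list of class `prior_config`.
#' @export
prior_config <- function(item_prior_sd = 10, trait_sd_scale = 5,
                         lkj_shape = 1, careless_shape_scale = 5,
                         dirichlet_base = c(1, 1), concentration_scale = 5) {
  scales <- c(item_prior_sd, trait_sd_scale, careless_shape_scale,
              concentration_scale)
  if (any(scales <= 0) || any(dirichlet_base <= 0) || lkj_shape <= 0)
    stop("all prior scales must be strictly positive", call. = FALSE)
  structure(list(item_prior_sd = item_prior_sd,
                 trait_sd_scale = trait_sd_scale,
                 lkj_shape = lkj_shape,
                 careless_shape_scale = careless_shape_scale,
                 dirichlet_base = dirichlet_base,
                 concentration_scale = concentration_scale),
            class = "prior_config")
}

half_cauchy_lpdf <- function(x, scale) {
  ifelse(x > 0, log(2 / (pi * scale)) - log1p((x / scale)^2), -Inf)
}

fit_item_meta <- function(items, n_items) {
  if (is.null(items))
    return(data.frame(wording = rep(1L, n_items),
                      dimension = rep(1L, n_items)))
  if (inherits(items, "vas_sim")) items <- items$items
  if (!is.data.frame(items))
    stop("`items` must be a data frame with wording (and dimension) columns",
         call. = FALSE)
  if (nrow(items) != n_items)
    stop("item metadata has ", nrow(items), " rows but the response matrix has ",
         n_items, " columns", call. = FALSE)
  wording <- if ("wording" %in% names(items)) as.integer(items$wording)
             else rep(1L, n_items)
  dimension <- if ("dimension" %in% names(items)) as.integer(items$dimension)
               else rep(1L, n_items)
  if (!all(wording %in% c(-1L, 1L)))
    stop("item wording must be -1 or +1", call. = FALSE)
  data.frame(wording = wording, dimension = dimension)
}

draw_colnames <- function(model, n_items, n_persons, n_dim) {
  J <- n_items; N <- n_persons; D <- n_dim
  nm <- switch(model,
    cfa_mixture = c(sprintf("nu[%d]", 1:J), sprintf("lambda[%d]", 1:J),
                    sprintf("sigma_item[%d]", 1:J), "mu_c", "sigma_c",
                    "pi", "omega", sprintf("theta[%d]", 1:N),
                    sprintf("pi_i[%d]", 1:N)),
    {
      corr <- character(0)
      if (D > 1) {
        for (d in 1:(D - 1)) for (e in (d + 1):D)
          corr <- c(corr, sprintf("R[%d,%d]", d, e))
      }
      th <- if (D == 1) sprintf("theta[%d]", 1:N)
            else as.vector(t(outer(1:N, 1:D,
                                   function(i, d) sprintf("theta[%d,%d]", i, d))))
      glob <- if (model == "mixture") c("m", "n", "pi", "omega") else character(0)
      pii <- if (model == "mixture") sprintf("pi_i[%d]", 1:N) else character(0)
      c(sprintf("b[%d]", 1:J), sprintf("alpha[%d]", 1:J),
        sprintf("sigma[%d]", 1:D), corr, glob, th, pii)
    })
  nm
}

#' Fit a Beta mixture IRM, a Beta IRM, or a normal mixture CFA
#'
#' The central model-fitting function.  `model = "mixture"` fits the Beta
#' mixture item response model: attentive responses follow a Beta IRM with a
#' logistic expected-response curve; careless responses follow a single
#' unstructured Beta(m, n) shared across persons and items; each person's
#' attentiveness probability receives a hierarchical Dirichlet (Beta) prior
#' centred on the population attentive proportion.  `model = "beta_irm"` drops
#' the careless component (every respondent treated as attentive).
#' `model = "cfa_mixture"` fits the deliberately mis-specified normal mixture
#' factor-analysis baseline, with loading signs constrained by item wording
#' and trait variance fixed to 1.
#'
#' Estimation is by adaptive random-walk Metropolis-within-Gibbs MCMC with the
#' class indicator marginalized out of the likelihood.  Trait means are fixed
#' at zero for identification.  The default chain length (2 chains of 4,000
#' iterations, half burn-in) is a desk-scale setting; production analyses
#' should use substantially longer chains (40,000 iterations with half
#' burn-in is a sound default) and check `$converged`.
#'
#' @param responses numeric person-by-item matrix with entries in (0, 1)
#'   (boundary values are squeezed inward by `clamp`); `NA` cells contribute
#'   nothing to the likelihood.
#' @param items item metadata: a data frame with columns `wording` (+1/-1)
#'   and `dimension`, an [item_params] table, or a `vas_sim` object.  `NULL`
#'   means all items positively worded on one dimension.
#' @param model one of `"mixture"`, `"beta_irm"`, `"cfa_mixture"`.
#' @param prior a [prior_config].
#' @param chains number of MCMC chains (at least 2 for convergence
#'   diagnostics).
#' @param iter iterations per chain.
#' @param burnin burn-in iterations discarded per chain (default half).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param clamp boundary squeeze constant for responses at 0 or 1.
#' @return an object of class `vasmix_fit` with components `draws` (list of
#'   per-chain draw matrices), `point` (posterior means), `ci95`, `epsr`,
#'   `converged` (all EPSR < 1.1), `person_prob` (posterior mean
#'   attentiveness probabilities), `theta` (posterior mean traits), plus the
#'   model, data and settings used.
#' @examples
#' \donttest{
#' sim <- simulate_vas(n_persons = 60, prop_careless = 0.2, seed = 7)
#' fit <- vasmix(sim$responses, sim$items, chains = 2, iter = 600, seed = 7)
#' summary(fit)
#' }
#' @export
vasmix <- function(responses, items = NULL,
                   model = c("mixture", "beta_irm", "cfa_mixture"),
                   prior = prior_config(), chains = 2L, iter = 4000L,
                   burnin = iter %/% 2L, thin = 1L, seed = 1L,
                   clamp = CLAMP) {
  model <- match.arg(model)
  y <- as.matrix(responses)
  storage.mode(y) <- "double"
  if (any(y < 0 | y > 1, na.rm = TRUE))
    stop("responses must lie in [0, 1]", call. = FALSE)
  y[!is.na(y)] <- clamp_unit(y[!is.na(y)], clamp)
  N <- nrow(y); J <- ncol(y)
  if (chains < 1L || iter <= burnin || burnin < 1L || thin < 1L)
    stop("invalid MCMC specification", call. = FALSE)
  meta <- fit_item_meta(items, J)
  D <- max(meta$dimension)
  if (model == "cfa_mixture" && D > 1L)
    stop("the CFA mixture baseline is unidimensional", call. = FALSE)

  t0 <- proc.time()[["elapsed"]]
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    # initialization near the attentive-dominant regime, jittered per chain
    jit <- function(x, s = 0.1) x + stats::rnorm(length(x), 0, s)
    if (model == "cfa_mixture") {
      init <- list(intercept = jit(rep(0.5, J)),
                   loading = meta$wording * exp(jit(rep(log(0.1), J))),
                   log_sigma_item = jit(rep(log(0.2), J)),
                   theta = jit(rep(0, N)),
                   careless_mean = 0.5 + stats::rnorm(1, 0, 0.05),
                   careless_sd = exp(jit(log(0.3), 0.1)),
                   pi = stats::plogis(jit(stats::qlogis(0.8))),
                   omega = exp(jit(log(2))),
                   person_prob = stats::plogis(jit(rep(stats::qlogis(0.9), N))))
      d <- .cfa_chain_cpp(y, meta$wording, prior, init,
                          as.integer(iter), as.integer(burnin),
                          as.integer(thin))
    } else {
      init <- list(difficulty = jit(rep(0, J)),
                   dispersion = jit(rep(0, J)),
                   theta = matrix(jit(rep(0, N * D)), N, D),
                   log_sigma = jit(rep(0, D)),
                   corr = diag(D),
                   m = exp(jit(0)), n = exp(jit(0)),
                   pi = stats::plogis(jit(stats::qlogis(0.8))),
                   omega = exp(jit(log(2))),
                   person_prob = stats::plogis(jit(rep(stats::qlogis(0.9), N))))
      d <- .mixture_chain_cpp(y, meta$wording, meta$dimension - 1L, D, prior,
                              init, as.integer(iter), as.integer(burnin),
                              as.integer(thin), model == "mixture")
    }
    colnames(d) <- draw_colnames(model, J, N, D)
    draws[[ch]] <- d
  }
  runtime <- proc.time()[["elapsed"]] - t0

  all_draws <- do.call(rbind, draws)
  point <- colMeans(all_draws)
  ci95 <- t(apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci95) <- c("2.5%", "97.5%")
  rhat <- if (chains >= 2L) epsr(draws) else
    stats::setNames(rep(NA_real_, ncol(all_draws)), colnames(all_draws))

  nm <- names(point)
  person_prob <- if (model == "beta_irm") rep(1, N)
                 else unname(point[grep("^pi_i\\[", nm)])
  theta_cols <- grep("^theta\\[", nm)
  theta <- matrix(point[theta_cols], N,
                  if (model == "cfa_mixture") 1L else D, byrow = (D > 1))

  structure(list(
    model = model, responses = y,
    draws = draws, point = point, ci95 = ci95, epsr = rhat,
    converged = if (chains >= 2L) all(rhat < 1.1, na.rm = TRUE) else NA,
    person_prob = person_prob, theta = theta,
    items = meta, n_persons = N, n_items = J, n_dim = D,
    prior = prior,
    mcmc = list(chains = chains, iter = iter, burnin = burnin, thin = thin,
                seed = seed),
    runtime = runtime, call = match.call()),
    class = "vasmix_fit")
}

structural_pars <- function(fit) {
  nm <- names(fit$point)
  nm[!grepl("^(theta|pi_i)\\[", nm)]
}

#' Gelman-Rubin potential scale reduction (EPSR)
#'
#' Computes the estimated potential scale reduction factor per parameter from
#' two or more chains of equal post-burn-in length: the square root of the
#' ratio of the pooled-variance estimate `(n-1)/n W + B/n` to the mean
#' within-chain variance `W`.  Values below 1.1 are conventionally taken as
#' satisfactory convergence.  `split = TRUE` halves each chain first
#' (split-chain variant, sensitive to within-chain trends).
#'
#' @param draws_by_chain list of numeric matrices (iterations x parameters),
#'   one per chain, with identical dimensions.
#' @param split halve each chain before computing the diagnostic?
#' @return named numeric vector of EPSR values, one per parameter.
#' @export
epsr <- function(draws_by_chain, split = FALSE) {
  if (!is.list(draws_by_chain) || length(draws_by_chain) < 2L)
    stop("EPSR needs at least two chains", call. = FALSE)
  dims <- vapply(draws_by_chain, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("chains must have identical dimensions", call. = FALSE)
  if (split) {
    half <- dims[1, 1] %/% 2L
    draws_by_chain <- unlist(lapply(draws_by_chain, function(m)
      list(m[seq_len(half), , drop = FALSE],
           m[half + seq_len(half), , drop = FALSE])), recursive = FALSE)
  }
  n <- nrow(draws_by_chain[[1]])
  means <- vapply(draws_by_chain, colMeans, numeric(dims[2, 1]))
  vars <- vapply(draws_by_chain, function(m) apply(m, 2, stats::var),
                 numeric(dims[2, 1]))
  if (is.null(dim(means))) {  # single parameter
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  names(rhat) <- colnames(draws_by_chain[[1]])
  rhat
}

#' @export
print.vasmix_fit <- function(x, ...) {
  lab <- switch(x$model, mixture = "Beta mixture IRM",
                beta_irm = "Beta IRM (attentive only)",
                cfa_mixture = "Normal mixture CFA baseline")
  cat(lab, sprintf("- %d persons, %d items, %d dimension(s)\n",
                   x$n_persons, x$n_items, x$n_dim))
  cat(sprintf("MCMC: %d chain(s) x %d iterations (%d burn-in), seed %d\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$burnin, x$mcmc$seed))
  cat("Converged (all EPSR < 1.1):", x$converged, "\n")
  if (x$model != "beta_irm") {
    cat(sprintf("Estimated attentive proportion: %.3f (careless %.3f)\n",
                x$point[["pi"]], 1 - x$point[["pi"]]))
    if (x$model == "mixture")
      cat(sprintf("Careless component: Beta(%.2f, %.2f)\n",
                  x$point[["m"]], x$point[["n"]]))
  }
  invisible(x)
}

#' @export
summary.vasmix_fit <- function(object, ...) {
  pars <- structural_pars(object)
  tab <- data.frame(mean = object$point[pars],
                    `2.5%` = object$ci95[pars, 1],
                    `97.5%` = object$ci95[pars, 2],
                    epsr = object$epsr[pars],
                    check.names = FALSE)
  out <- list(model = object$model, table = tab,
              converged = object$converged,
              max_epsr = max(object$epsr, na.rm = TRUE))
  class(out) <- "summary.vasmix_fit"
  out
}

#' @export
print.summary.vasmix_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (structural parameters), model:", x$model, "\n")
  print(round(x$table, digits))
  cat(sprintf("\nMax EPSR over all stored parameters: %.3f (converged: %s)\n",
              x$max_epsr, x$converged))
  invisible(x)
}

#' @export
coef.vasmix_fit <- function(object, ...) {
  pars <- structural_pars(object)
  object$point[pars]
}

#' Posterior-mean residuals
#'
#' Observed responses minus the expected attentive response evaluated at the
#' posterior means of the item parameters and traits.  Careless rows are
#' expected to leave large structured residuals under the attentive model.
#'
#' @param object a `vasmix_fit`.
#' @param ... unused.
#' @return numeric person-by-item matrix.
#' @export
residuals.vasmix_fit <- function(object, ...) {
  J <- object$n_items; N <- object$n_persons
  mu <- matrix(NA_real_, N, J)
  if (object$model == "cfa_mixture") {
    nu <- object$point[sprintf("nu[%d]", 1:J)]
    lam <- object$point[sprintf("lambda[%d]", 1:J)]
    for (i in seq_len(N)) mu[i, ] <- nu + lam * object$theta[i, 1]
  } else {
    b <- object$point[sprintf("b[%d]", 1:J)]
    it <- item_params(b, 0, object$items$wording, object$items$dimension)
    for (i in seq_len(N)) mu[i, ] <- expected_response(object$theta[i, ], it)
  }
  res <- object$responses - mu
  attr(res, "fitted") <- mu
  res
}

#' Simulate response matrices from a fitted model
#'
#' Draws replicate person-by-item response matrices from the fitted model at
#' its posterior means: each cell is attentive with the person's posterior
#' attentiveness probability and is then drawn from the corresponding
#' component.
#'
#' @param object a `vasmix_fit`.
#' @param nsim number of replicate matrices.
#' @param seed optional integer RNG seed.
#' @param ... unused.
#' @return a list of `nsim` response matrices.
#' @export
simulate.vasmix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$n_persons; J <- object$n_items
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    y <- matrix(NA_real_, N, J)
    att <- matrix(stats::runif(N * J) < object$person_prob, N, J)
    if (object$model == "cfa_mixture") {
      nu <- object$point[sprintf("nu[%d]", 1:J)]
      lam <- object$point[sprintf("lambda[%d]", 1:J)]
      sj <- object$point[sprintf("sigma_item[%d]", 1:J)]
      for (i in seq_len(N)) {
        mu <- nu + lam * object$theta[i, 1]
        y[i, ] <- ifelse(att[i, ], stats::rnorm(J, mu, sj),
                         stats::rnorm(J, object$point[["mu_c"]],
                                      object$point[["sigma_c"]]))
      }
    } else {
      b <- object$point[sprintf("b[%d]", 1:J)]
      al <- object$point[sprintf("alpha[%d]", 1:J)]
      it <- item_params(b, al, object$items$wording, object$items$dimension)
      m <- if (object$model == "mixture") object$point[["m"]] else 1
      n <- if (object$model == "mixture") object$point[["n"]] else 1
      for (i in seq_len(N)) {
        sp <- shape_params(object$theta[i, ], it)
        ya <- stats::rbeta(J, sp$accept, sp$refuse)
        yc <- stats::rbeta(J, m, n)
        y[i, ] <- clamp_unit(ifelse(att[i, ], ya, yc))
      }
    }
    out[[s]] <- y
  }
  out
}

#' Plot method for fitted models
#'
#' `type = "careless"` overlays the estimated careless Beta density on a
#' histogram of all responses from persons flagged by the 0.5 threshold rule;
#' `type = "icc"` draws the posterior-mean item characteristic curves;
#' `type = "trace"` shows trace plots of selected parameters per chain.
#'
#' @param x a `vasmix_fit`.
#' @param type plot type.
#' @param pars parameter names for `type = "trace"` (default: the global
#'   mixture parameters).
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.vasmix_fit <- function(x, type = c("careless", "icc", "trace"),
                            pars = NULL, ...) {
  type <- match.arg(type)
  if (type == "careless") {
    if (x$model != "mixture")
      stop("careless-density plot needs a mixture fit", call. = FALSE)
    grid <- seq(0.001, 0.999, length.out = 400)
    graphics::plot(grid, stats::dbeta(grid, x$point[["m"]], x$point[["n"]]),
                   type = "l", xlab = "response",
                   ylab = "density",
                   main = sprintf("Estimated careless component: Beta(%.2f, %.2f)",
                                  x$point[["m"]], x$point[["n"]]), ...)
  } else if (type == "icc") {
    J <- x$n_items
    b <- x$point[sprintf("b[%d]", 1:J)]
    th <- seq(-3, 3, length.out = 121)
    graphics::plot(range(th), c(0, 1), type = "n", xlab = "trait",
                   ylab = "expected response",
                   main = "Posterior-mean item characteristic curves", ...)
    for (j in seq_len(J))
      graphics::lines(th, stats::plogis(x$items$wording[j] * th - b[j]),
                      col = j)
  } else {
    if (is.null(pars))
      pars <- intersect(c("m", "n", "pi", "omega", "mu_c", "sigma_c"),
                        names(x$point))
    old <- graphics::par(mfrow = c(length(pars), 1),
                         mar = c(2.5, 4, 1.5, 1))
    on.exit(graphics::par(old))
    for (p in pars) {
      rng <- range(vapply(x$draws, function(d) range(d[, p]), numeric(2)))
      graphics::plot(x$draws[[1]][, p], type = "l", ylim = rng, ylab = p,
                     xlab = "", ...)
      if (length(x$draws) > 1)
        for (ch in 2:length(x$draws))
          graphics::lines(x$draws[[ch]][, p], col = ch)
    }
  }
  invisible(x)
}
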