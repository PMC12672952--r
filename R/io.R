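#' Read a response table from CSV
#'
#' Expects a header row of item ids with the first column holding person ids.
#' Values must lie in the closed interval \[0, 1\] (what slider software
#' exports); exact 0s and 1s are squeezed inward by the documented clamp so
#' that Beta log-densities are finite, and the number of clamped cells is
#' reported.  Rows with no observed responses at all are dropped (and
#' counted); partially missing rows are kept, missing cells simply contribute
#' nothing to the likelihood.
#'
#' @param path CSV file path.
#' @param clamp boundary squeeze constant.
#' @param quiet suppress the clamping/dropping messages?
#' @return numeric matrix of responses with person-id rownames and item-id
#'   colnames, entries strictly inside (0, 1) or `NA`.
#' @export
read_responses <- function(path, clamp = CLAMP, quiet = FALSE) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("response file needs a person-id column plus at least one item",
         call. = FALSE)
  ids <- as.character(tab[[1]])
  y <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(y)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1L]]))) &
                 !is.na(tab[[bad + 1L]]))[1]
    stop(sprintf("non-numeric value in column '%s' (row %s)",
                 names(tab)[bad + 1L], ifelse(is.na(row), "?", row)),
         call. = FALSE)
  }
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    bad <- which(y < 0 | y > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("response outside [0, 1] at row %d, column '%s'",
                 bad[1], colnames(y)[bad[2]]), call. = FALSE)
  }
  rownames(y) <- ids
  n_clamped <- sum(y == 0 | y == 1, na.rm = TRUE)
  y[!is.na(y)] <- clamp_unit(y[!is.na(y)], clamp)
  empty <- rowSums(!is.na(y)) == 0L
  if (!quiet) {
    if (n_clamped) message(n_clamped, " boundary value(s) squeezed into [",
                           clamp, ", ", 1 - clamp, "]")
    if (any(empty)) message(sum(empty), " all-missing row(s) dropped")
  }
  y[!empty, , drop = FALSE]
}

#' Write a response table to CSV
#'
#' Inverse of [read_responses]: person ids in the first column, item ids in
#' the header.
#'
#' @param responses numeric matrix (rownames used as person ids).
#' @param path output CSV path.
#' @export
write_responses <- function(responses, path) {
  ids <- rownames(responses)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(responses)))
  tab <- data.frame(person = ids, responses, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read item metadata (wording and dimension) from CSV or JSON
#'
#' The file must provide one record per item with fields `item` (id),
#' `wording` (+1/-1) and optionally `dimension`.
#'
#' @param path CSV or JSON file path.
#' @param item_ids optional character vector of expected item ids (e.g.
#'   response-matrix colnames); validated and used to order the rows.
#' @return a data frame with columns `item`, `wording`, `dimension`.
#' @export
read_item_metadata <- function(path, item_ids = NULL) {
  meta <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "wording") %in% names(meta)))
    stop("item metadata needs fields 'item' and 'wording'", call. = FALSE)
  if (!"dimension" %in% names(meta)) meta$dimension <- 1L
  meta$wording <- as.integer(meta$wording)
  if (!all(meta$wording %in% c(-1L, 1L)))
    stop("item wording must be -1 or +1", call. = FALSE)
  if (!is.null(item_ids)) {
    if (!setequal(meta$item, item_ids))
      stop("item metadata does not match the response columns", call. = FALSE)
    meta <- meta[match(item_ids, meta$item), ]
    rownames(meta) <- NULL
  }
  meta
}

config_defaults <- function() {
  list(
    prior = unclass(prior_config()),
    mcmc = list(chains = 2L, iter = 4000L, burnin = NULL, thin = 1L,
                epsr_threshold = 1.1),
    simulate = list(n_persons = 300L, n_items = 10L, n_negative = 5L,
                    pattern = "beta_extremes", prop_careless = 0.25,
                    clamp = CLAMP),
    study = list(patterns = c("beta_extremes", "end_preference",
                              "midpoint_normal"),
                 proportions = c(0.05, 0.10, 0.15, 0.25, 0.40),
                 n_replications = 2L))
}

#' Load a run configuration from YAML or JSON
#'
#' Sections `prior`, `mcmc`, `simulate` and `study` with the package defaults
#' filled in for anything omitted; unknown sections or keys are rejected so
#' typos fail loudly.  An empty file yields the full default configuration.
#'
#' @param path YAML or JSON configuration file; `NULL` gives the defaults.
#' @return a named list of class `vasmix_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- config_defaults()
  bad_sec <- setdiff(names(user), names(defaults))
  if (length(bad_sec))
    stop("unknown configuration section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (is.null(defaults$mcmc$burnin))
    defaults$mcmc$burnin <- defaults$mcmc$iter %/% 2L
  if (defaults$mcmc$chains < 2L)
    stop("at least 2 chains are required for the EPSR convergence check",
         call. = FALSE)
  structure(defaults, class = "vasmix_config")
}

config_hash <- function(config) {
  # small order-independent fingerprint so outputs can name the config
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Write a machine-readable summary of a fit or study
#'
#' For a `vasmix_fit`: JSON with posterior means, 95% credible intervals,
#' EPSR values, the convergence flag, the seeds and settings used, and a
#' schema version.  For a `vasmix_study`: the same JSON wrapper around the
#' cell table, plus the cell and replication tables as CSV files alongside
#' (same stem, `_cells.csv` / `_replications.csv`).
#'
#' @param result a `vasmix_fit` or `vasmix_study`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  if (inherits(result, "vasmix_fit")) {
    out <- list(schema = "vascareless-fit-1",
                model = result$model,
                point = as.list(result$point),
                ci95 = list(lower = as.list(result$ci95[, 1]),
                            upper = as.list(result$ci95[, 2])),
                epsr = as.list(result$epsr),
                converged = result$converged,
                person_prob = result$person_prob,
                mcmc = result$mcmc,
                prior = unclass(result$prior),
                config_hash = config_hash(unclass(result$prior)))
  } else if (inherits(result, "vasmix_study")) {
    stem <- sub("\\.json$", "", path)
    utils::write.csv(result$cells, paste0(stem, "_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(result$replications, paste0(stem, "_replications.csv"),
                     row.names = FALSE)
    out <- list(schema = "vascareless-study-1",
                settings = result$settings,
                cells = result$cells,
                config_hash = config_hash(result$settings))
  } else stop("write_summary handles vasmix_fit or vasmix_study objects",
              call. = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a simulated dataset (responses CSV plus truth sidecar JSON)
#'
#' @param sim a `vas_sim`.
#' @param path output CSV path for the responses; the generating truth
#'   (items, traits, membership, condition) goes to the same stem with
#'   `_truth.json`.
#' @export
write_simulation <- function(sim, path) {
  write_responses(sim$responses, path)
  truth <- list(schema = "vascareless-sim-1",
                items = sim$items,
                traits = sim$traits,
                membership = as.character(sim$membership),
                condition = c(sim$condition[c("n_persons", "n_items",
                                              "n_negative", "prop_careless",
                                              "seed", "clamp")],
                              list(pattern = sim$condition$pattern$kind)))
  jsonlite::write_json(truth, paste0(sub("\\.csv$", "", path), "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
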