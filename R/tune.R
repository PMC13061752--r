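# Hyperparameter search with the validation detection F1 as objective.

#' Define a hyperparameter search space
#'
#' Each entry is either a categorical set (`values = c(...)`) or a
#' bounded range (`lower`, `upper`, optionally `log = TRUE`).
#'
#' @param ... Named lists, e.g.
#'   `radius_mm = list(values = c(1, 2, 3))` or
#'   `lr = list(lower = 1e-4, upper = 1e-2, log = TRUE)`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(...) {
  sp <- list(...)
  if (length(sp) == 0L || is.null(names(sp)) || any(names(sp) == "")) {
    stop("all search-space entries must be named", call. = FALSE)
  }
  for (nm in names(sp)) {
    e <- sp[[nm]]
    if (!is.null(e$values)) {
      if (length(e$values) == 0L) stop(sprintf("'%s': empty categorical set", nm), call. = FALSE)
    } else if (!is.null(e$lower) && !is.null(e$upper)) {
      if (!is.finite(e$lower) || !is.finite(e$upper) || e$lower >= e$upper) {
        stop(sprintf("'%s': bounds must be finite with lower < upper", nm), call. = FALSE)
      }
    } else {
      stop(sprintf("'%s': give either `values` or `lower`/`upper`", nm), call. = FALSE)
    }
  }
  structure(sp, class = "search_space")
}

sample_params <- function(space) {
  out <- list()
  for (nm in names(space)) {
    e <- space[[nm]]
    out[[nm]] <- if (!is.null(e$values)) {
      e$values[[sample.int(length(e$values), 1L)]]
    } else if (isTRUE(e$log)) {
      exp(stats::runif(1, log(e$lower), log(e$upper)))
    } else {
      stats::runif(1, e$lower, e$upper)
    }
  }
  out
}

#' Random-search hyperparameter tuning on a validation objective
#'
#' Runs `n_trials` seeded random draws from the search space and scores
#' each with `objective` (higher is better; by convention the
#' validation micro-F1 at the 2 mm matching radius). Failed trials are
#' recorded with `NA`; if every trial fails, an error with the
#' per-trial diagnostics is raised.
#'
#' @param space A [search_space()].
#' @param n_trials Number of trials (>= 1).
#' @param objective `function(params) -> numeric scalar` where `params`
#'   is a named list drawn from the space.
#' @param seed Integer seed making the trial sequence reproducible.
#' @param sampler `"random"` (independent draws, works for any space)
#'   or `"grid"` (shuffled enumeration of the Cartesian product of
#'   categorical values, cycled to `n_trials`; all entries must be
#'   categorical).
#' @return An object of class `tune_result`: list with `best_params`,
#'   `best_value`, `best_trial`, and `trials` (data frame of parameter
#'   draws and objective values).
#' @export
tune_hyperparameters <- function(space, n_trials, objective, seed = 1L,
                                 sampler = c("random", "grid")) {
  stopifnot(inherits(space, "search_space"))
  sampler <- match.arg(sampler)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  set.seed(seed)
  draws <- if (sampler == "grid") {
    if (!all(vapply(space, function(e) !is.null(e$values), logical(1)))) {
      stop("grid sampling needs categorical `values` for every entry", call. = FALSE)
    }
    grid <- expand.grid(lapply(space, function(e) seq_along(e$values)),
                        KEEP.OUT.ATTRS = FALSE)
    ord <- rep_len(sample(nrow(grid)), n_trials)
    lapply(ord, function(i) {
      stats::setNames(lapply(names(space), function(nm)
        space[[nm]]$values[[grid[i, nm]]]), names(space))
    })
  } else {
    replicate(n_trials, sample_params(space), simplify = FALSE)
  }
  values <- numeric(n_trials)
  errors <- character(n_trials)
  for (i in seq_len(n_trials)) {
    res <- tryCatch(objective(draws[[i]]),
                    error = function(e) structure(NA_real_, msg = conditionMessage(e)))
    values[i] <- as.numeric(res)
    errors[i] <- if (is.na(values[i])) attr(res, "msg") %||% "NA objective" else ""
  }
  if (all(is.na(values))) {
    stop(paste0("all trials failed:\n",
                paste(sprintf("  trial %d: %s", seq_len(n_trials), errors),
                      collapse = "\n")), call. = FALSE)
  }
  trials <- cbind(data.frame(trial = seq_len(n_trials)),
                  do.call(rbind, lapply(draws, function(d)
                    as.data.frame(d, stringsAsFactors = FALSE))),
                  data.frame(value = values, error = errors))
  best <- which.max(values)
  structure(list(best_params = draws[[best]], best_value = values[best],
                 best_trial = best, trials = trials),
            class = "tune_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d trial(s); best value %.4f at trial %d\n",
              nrow(x$trials), x$best_value, x$best_trial))
  ps <- vapply(names(x$best_params),
               function(k) sprintf("%s = %s", k, format(x$best_params[[k]])),
               character(1))
  cat("  ", paste(ps, collapse = ", "), "\n")
  invisible(x)
}
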