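## Randomized source-host logistic regression: the probability that a host
## genus is attacked by a fly declines with its phylogenetic distance from a
## randomly chosen source host of that fly. Each run picks one source per
## fly, pools rows across flies, and fits logit P(attack) = b0 + b1 *
## log10(distance + 1); coefficients are averaged over runs and intervals
## taken as percentiles of the run-level estimates.

#' Assemble one randomized source-host dataset
#'
#' For every fly with at least `min_hosts` host genera, one of its hosts is
#' drawn uniformly as the source; every other genus in the interaction
#' matrix becomes a target row with response 1 if the fly attacks it and
#' predictor log10(patristic distance from source + 1), distance in the
#' units of `distances` (million years for a host chronogram).
#'
#' @param matrix binary fly-by-genus interaction matrix
#'   (see [interaction_matrix()]).
#' @param distances symmetric patristic distance matrix covering every genus
#'   column of `matrix`.
#' @param min_hosts flies with fewer host genera contribute no rows
#'   (default 3).
#' @return data.frame of class `sharing_dataset` with columns `fly`,
#'   `source_genus`, `target_genus`, `response`, `x`.
#' @export
build_run_dataset <- function(matrix, distances, min_hosts = 3) {
  stopifnot(is.matrix(matrix), is.matrix(distances))
  genera <- colnames(matrix)
  missing <- setdiff(genera, rownames(distances))
  if (length(missing))
    stop("genus missing from distance matrix: ",
         paste(head(missing, 10), collapse = ", "))
  flies <- rownames(matrix)
  keep <- rowSums(matrix) >= min_hosts
  out <- vector("list", sum(keep))
  j <- 0L
  for (f in flies[keep]) {
    hosts <- genera[matrix[f, ] == 1L]
    src <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
    targets <- setdiff(genera, src)
    j <- j + 1L
    out[[j]] <- data.frame(
      fly = f, source_genus = src, target_genus = targets,
      response = as.integer(matrix[f, targets] == 1L),
      x = log10(distances[src, targets] + 1),
      stringsAsFactors = FALSE)
  }
  ds <- if (j) do.call(rbind, out) else
    data.frame(fly = character(), source_genus = character(),
               target_genus = character(), response = integer(),
               x = numeric())
  rownames(ds) <- NULL
  class(ds) <- c("sharing_dataset", "data.frame")
  ds
}

#' Fit the host-sharing logistic regression to one dataset
#'
#' Maximum-likelihood fit of logit P(response = 1) = b0 + b1 x by
#' iteratively reweighted least squares (base R's `glm.fit`, tightened
#' convergence, 100 iteration cap). Runs showing non-convergence or
#' separation (divergent coefficients) are flagged rather than trusted.
#'
#' @param dataset a `sharing_dataset`.
#' @return list with `beta0`, `beta1`, `flagged` (logical), `n_rows`.
#' @export
fit_logistic <- function(dataset) {
  stopifnot(inherits(dataset, "sharing_dataset"))
  y <- dataset$response
  x <- dataset$x
  if (!nrow(dataset)) stop("empty dataset")
  if (length(unique(y)) < 2L)
    stop("both response classes must be present")
  if (diff(range(x)) == 0)
    stop("all predictor values identical: design matrix is rank deficient")
  fit <- suppressWarnings(
    glm.fit(cbind(1, x), y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100)))
  co <- fit$coefficients
  flagged <- !fit$converged || fit$boundary || any(!is.finite(co)) ||
    any(abs(co) > 30)
  list(beta0 = unname(co[1]), beta1 = unname(co[2]),
       flagged = flagged, n_rows = nrow(dataset))
}

#' Randomized source-host regression over many runs
#'
#' Repeats [build_run_dataset()] + [fit_logistic()] `n_runs` times with a
#' fresh random source host per fly each run; reports the arithmetic mean of
#' the run-level coefficients and their 2.5/97.5 percentile interval.
#' Flagged runs are excluded from pooling (and counted).
#'
#' @inheritParams build_run_dataset
#' @param n_runs number of randomized runs (default 1000).
#' @param seed integer seed; the whole procedure is reproducible given it.
#' @return object of class `sharing_fit`: run-level coefficients (`runs`),
#'   pooled `beta0`/`beta1`, `ci_beta0`/`ci_beta1`, `n_runs`, `n_flagged`,
#'   `n_flies`, `seed`.
#' @export
resample_regression <- function(matrix, distances, n_runs = 1000,
                                min_hosts = 3, seed = NULL) {
  stopifnot(n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_flies <- sum(rowSums(matrix) >= min_hosts)
  if (!n_flies) stop("no fly has >= ", min_hosts, " host genera")
  b0 <- b1 <- numeric(n_runs)
  flagged <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    ds <- build_run_dataset(matrix, distances, min_hosts)
    f <- fit_logistic(ds)
    b0[r] <- f$beta0; b1[r] <- f$beta1; flagged[r] <- f$flagged
  }
  if (mean(flagged) > 0.10)
    warning(sprintf("%.1f%% of runs flagged (separation/non-convergence)",
                    100 * mean(flagged)))
  ok <- !flagged
  if (!any(ok)) stop("all runs flagged; no pooled estimate")
  structure(list(
    runs = data.frame(run = seq_len(n_runs), beta0 = b0, beta1 = b1,
                      flagged = flagged),
    beta0 = mean(b0[ok]), beta1 = mean(b1[ok]),
    ci_beta0 = unname(quantile(b0[ok], c(0.025, 0.975))),
    ci_beta1 = unname(quantile(b1[ok], c(0.025, 0.975))),
    n_runs = n_runs, n_flagged = sum(flagged),
    n_flies = n_flies, seed = seed,
    ci_method = "percentile (2.5/97.5) of run-level coefficients"),
    class = "sharing_fit")
}

#' Predicted host-sharing probability at a phylogenetic distance
#'
#' Inverse-logit of b0 + b1 log10(distance + 1); strictly decreasing in
#' distance whenever b1 < 0.
#'
#' @param fit a `sharing_fit`, or any list with `beta0` and `beta1`.
#' @param distance non-negative distance(s), same units as the fit (Myr).
#' @return probability vector.
#' @export
sharing_probability <- function(fit, distance) {
  stopifnot(all(distance >= 0))
  plogis(fit$beta0 + fit$beta1 * log10(distance + 1))
}

#' @export
print.sharing_fit <- function(x, ...) {
  cat(sprintf(
    "Host-sharing regression over %d runs (%d flies):\n", x$n_runs, x$n_flies))
  cat(sprintf("  logit(S) = %.4f %+.4f * log10(distance + 1)\n",
              x$beta0, x$beta1))
  cat(sprintf("  95%% interval beta0: [%.4f, %.4f]  beta1: [%.4f, %.4f]\n",
              x$ci_beta0[1], x$ci_beta0[2], x$ci_beta1[1], x$ci_beta1[2]))
  if (x$n_flagged) cat("  flagged runs excluded:", x$n_flagged, "\n")
  invisible(x)
}
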