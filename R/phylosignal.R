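## Phylogenetic signal: Blomberg's K with a randomization test and Pagel's
## lambda with an ML fit and likelihood-ratio test. Both operate on the
## Brownian-motion covariance matrix V of the tree; binary polyphagy states
## are analysed as numeric 0/1 traits with the same machinery (a recognised
## approximation, flagged with a warning).

# align a named trait vector with the tree tips; basic sanity checks
.align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be a named vector (tip labels)")
  labs <- tree$tip.label
  missing <- setdiff(labs, names(trait))
  if (length(missing))
    stop("trait missing for tip(s): ", paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(names(trait), labs)
  if (length(extra))
    stop("trait has values for unknown tip(s): ",
         paste(head(extra, 5), collapse = ", "))
  y <- as.numeric(trait[labs])
  if (anyNA(y)) stop("trait contains missing values")
  if (sd(y) == 0) stop("trait is constant; signal statistics are undefined")
  y
}

# covariance matrix with zero-length terminal branches jittered so V is
# invertible after polytomy resolution
.signal_V <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- ape::Ntip(tree)
  term <- tree$edge[, 2] <= ntip
  if (any(tree$edge.length[term] == 0)) {
    h <- max(ape::node.depth.edgelength(tree))
    warning("zero-length terminal branch(es) jittered by 1e-8 x tree height")
    tree$edge.length[term & tree$edge.length == 0] <- 1e-8 * h
  }
  phylo_covariance(tree)
}

# precomputed pieces of the K statistic that do not depend on the trait
.k_setup <- function(V) {
  n <- nrow(V)
  ch <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is singular; jitter zero-length branches ",
         "or drop duplicate tips (", conditionMessage(e), ")"))
  Vinv <- chol2inv(ch)
  ones <- rep(1, n)
  iV1 <- Vinv %*% ones
  sum_iV <- sum(iV1)
  expected <- (sum(diag(V)) - n / sum_iV) / (n - 1)
  list(n = n, Vinv = Vinv, iV1 = as.numeric(iV1), sum_iV = sum_iV,
       expected = expected)
}

.k_stat <- function(y, s) {
  a_hat <- sum(s$iV1 * y) / s$sum_iV
  r <- y - a_hat
  mse0 <- sum(r^2) / (s$n - 1)
  mse <- as.numeric(t(r) %*% s$Vinv %*% r) / (s$n - 1)
  (mse0 / mse) / s$expected
}

#' Blomberg's K
#'
#' Variance-ratio statistic for phylogenetic signal in a continuous (or 0/1)
#' trait: the ratio of the ordinary to the phylogenetically corrected mean
#' squared error, scaled by its Brownian-motion expectation so that K is
#' calibrated to 1 under Brownian evolution on the given tree. K near 0
#' indicates phylogenetic independence; K > 1 stronger-than-Brownian
#' resemblance among relatives.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param trait named numeric vector over the tree tips.
#' @return the K statistic (non-negative scalar).
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(tree, trait) {
  y <- .align_trait(tree, trait)
  if (length(y) < 3) stop("need at least 3 tips")
  if (all(y %in% c(0, 1)))
    warning("binary trait analysed with continuous-trait machinery")
  s <- .k_setup(.signal_V(tree))
  .k_stat(y, s)
}

#' Randomization test for Blomberg's K
#'
#' Permutes trait values across tips and reports the add-one permutation
#' p-value for the one-sided alternative that the observed K is high:
#' p = (1 + #\{K_perm >= K_obs\}) / (1 + n_perm).
#'
#' @inheritParams blomberg_k
#' @param n_perm number of randomizations (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `signal_result`: list with `method`, `statistic`,
#'   `p_value`, `n_tips`, `n_randomizations`, `seed`.
#' @export
blomberg_k_test <- function(tree, trait, n_perm = 10000, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  y <- .align_trait(tree, trait)
  if (length(y) < 3) stop("need at least 3 tips")
  s <- .k_setup(.signal_V(tree))
  k_obs <- .k_stat(y, s)
  if (!is.null(seed)) set.seed(seed)
  k_perm <- vapply(seq_len(n_perm),
                   function(i) .k_stat(sample(y), s), numeric(1))
  p <- (1 + sum(k_perm >= k_obs)) / (1 + n_perm)
  structure(list(method = "blomberg_K", statistic = k_obs, p_value = p,
                 n_tips = s$n, n_randomizations = n_perm, seed = seed),
            class = "signal_result")
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies off-diagonal entries of V by lambda, leaving the diagonal
#' unchanged; lambda = 1 returns V, lambda = 0 a star phylogeny.
#'
#' @param V phylogenetic covariance matrix.
#' @param lam lambda in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lam) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop("lambda must lie in [0, 1]")
  Vl <- V * lam
  diag(Vl) <- diag(V)
  Vl
}

# profiled MVN log-likelihood of trait y with covariance sigma2 * V(lambda)
.lambda_loglik <- function(y, V, lam) {
  Vl <- lambda_transform(V, lam)
  ch <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  n <- length(y)
  logdet <- 2 * sum(log(diag(ch)))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a_hat <- sum(Vinv_y) / sum(Vinv_1)
  r <- y - a_hat
  Vinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vinv_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the multiplier lambda on the off-diagonal phylogenetic covariance by
#' maximizing the multivariate-normal likelihood of the trait, with the
#' ancestral mean and rate profiled out analytically. The search is bounded
#' to \[0, 1\]; endpoints are evaluated explicitly so boundary optima (the
#' common empirical outcome lambda = 1) are returned exactly. On a star
#' phylogeny the likelihood is flat in lambda; this is detected and reported
#' (`flat = TRUE`, `lambda = NA`) rather than returning an arbitrary value.
#'
#' @inheritParams blomberg_k
#' @return object of class `lambda_fit`: list with `lambda`, `logL`,
#'   `logL0` (lambda = 0), `logL1` (lambda = 1), `n_tips`, `flat`.
#' @references Pagel (1999) Nature 401:877-884.
#' @export
pagel_lambda <- function(tree, trait) {
  y <- .align_trait(tree, trait)
  if (length(y) < 3) stop("need at least 3 tips")
  V <- .signal_V(tree)
  offdiag <- V; diag(offdiag) <- 0
  if (max(abs(offdiag)) < 1e-12 * max(diag(V))) {
    warning("star phylogeny: likelihood is flat in lambda")
    ll <- .lambda_loglik(y, V, 0)
    return(structure(list(lambda = NA_real_, logL = ll, logL0 = ll,
                          logL1 = ll, n_tips = length(y), flat = TRUE),
                     class = "lambda_fit"))
  }
  f <- function(l) .lambda_loglik(y, V, l)
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand_l <- c(0, opt$maximum, 1)
  cand_ll <- c(f(0), opt$objective, f(1))
  best <- which.max(cand_ll)
  structure(list(lambda = cand_l[best], logL = cand_ll[best],
                 logL0 = cand_ll[1], logL1 = cand_ll[3],
                 n_tips = length(y), flat = FALSE),
            class = "lambda_fit")
}

#' Likelihood-ratio test for Pagel's lambda
#'
#' One-sided test of lambda-hat against lambda = 0 (phylogenetic
#' independence): 2 (logL(lambda-hat) - logL(0)) referred to chi-squared
#' with 1 degree of freedom.
#'
#' @inheritParams blomberg_k
#' @param fit optional precomputed [pagel_lambda()] result.
#' @return object of class `signal_result` with the lambda estimate as
#'   `statistic` and the LRT `p_value` (`df = 1`).
#' @export
pagel_lambda_test <- function(tree, trait, fit = NULL) {
  if (is.null(fit)) fit <- pagel_lambda(tree, trait)
  stopifnot(inherits(fit, "lambda_fit"))
  if (isTRUE(fit$flat))
    stop("likelihood is flat in lambda (star phylogeny); no test possible")
  lr <- max(0, 2 * (fit$logL - fit$logL0))
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(method = "pagel_lambda", statistic = fit$lambda,
                 p_value = p, n_tips = fit$n_tips, df = 1, LR = lr),
            class = "signal_result")
}

#' Signal summary over breadth partitions
#'
#' Convenience wrapper reproducing the standard presentation: the continuous
#' family-breadth trait plus its binary polyphagy partitions at the given
#' thresholds, each tested with Blomberg's K (randomization) and Pagel's
#' lambda (LRT).
#'
#' @param tree fly phylogeny (`phylo`).
#' @param table an `association_table` whose flies match the tree tips.
#' @param thresholds integer thresholds for the polyphagy partitions.
#' @param n_perm randomizations for the K test.
#' @param seed integer seed.
#' @return data.frame with one row per character: `character`,
#'   `n_polyphagous`, `K`, `p_K`, `lambda`, `p_lambda`.
#' @export
signal_table <- function(tree, table, thresholds = c(2, 3, 4),
                         n_perm = 10000, seed = NULL) {
  prof <- host_breadth(table)
  traits <- c(
    list(continuous = setNames(as.numeric(prof$n_host_families),
                               prof$fly_species)),
    setNames(lapply(thresholds, function(th)
      binarize_polyphagy(prof, th)$trait + 0.0),
      paste0("more_than_", thresholds, "_families"))
  )
  rows <- lapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    if (sd(tr) == 0) {
      .msg("character '", names(traits)[i],
           "' is constant across flies; statistics undefined, reported NA")
      return(data.frame(character = names(traits)[i],
                        n_polyphagous = if (i == 1) NA_integer_
                                        else sum(tr > 0),
                        K = NA_real_, p_K = NA_real_,
                        lambda = NA_real_, p_lambda = NA_real_,
                        stringsAsFactors = FALSE))
    }
    kt <- suppressWarnings(blomberg_k_test(tree, tr, n_perm = n_perm,
                                           seed = if (is.null(seed)) NULL
                                                  else seed + i))
    lf <- suppressWarnings(pagel_lambda(tree, tr))
    lt <- pagel_lambda_test(tree, tr, fit = lf)
    data.frame(character = names(traits)[i],
               n_polyphagous = if (i == 1) NA_integer_ else sum(tr > 0),
               K = kt$statistic, p_K = kt$p_value,
               lambda = lf$lambda, p_lambda = lt$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n_tips))
  invisible(x)
}

#' @export
print.lambda_fit <- function(x, ...) {
  if (isTRUE(x$flat)) {
    cat("Pagel's lambda: flat likelihood (star phylogeny), no estimate\n")
  } else {
    cat(sprintf("Pagel's lambda = %.4f (logL %.4f; logL0 %.4f)\n",
                x$lambda, x$logL, x$logL0))
  }
  invisible(x)
}
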