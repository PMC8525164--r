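## DEC* likelihood, ML rate estimation, and marginal ancestral ranges.
##
## The pruning pass propagates conditional likelihoods along branches with
## the action of the matrix exponential computed by uniformization on the
## sparse generator (exact to the series truncation, here 1e-14 Poisson
## tail), which keeps the 511-state space of 9 families tractable. Internal
## nodes mix daughter partials through the cladogenetic event table; partial
## vectors are rescaled per node with accumulated log-scalers to avoid
## underflow.

# action of exp(Qt) (or its transpose) on vector v. Two engines: an
# eigendecomposition of Q (small state spaces; reused across branches) and
# uniformization on the sparse generator (large spaces, or defective Q):
# Q = Omega (M - I) with M nonnegative, series weights Poisson(Omega t).
.exp_action <- function(gen, t, v, transpose = FALSE) {
  if (gen$type == "eigen") {
    ex <- exp(gen$lam * t)
    out <- if (transpose) crossprod(gen$Uinv, ex * crossprod(gen$U, v))
           else gen$U %*% (ex * (gen$Uinv %*% v))
    return(pmax(Re(as.vector(out)), 0))
  }
  lam <- gen$Omega * t
  if (lam == 0) return(v)
  K <- max(10L, ceiling(lam + 12 * sqrt(lam) + 20))
  w <- dpois(0:K, lam)
  res <- w[1] * v
  vk <- v
  for (k in seq_len(K)) {
    vk <- if (transpose) as.numeric(Matrix::crossprod(gen$M, vk))
          else as.numeric(gen$M %*% vk)
    if (w[k + 1] > 0) res <- res + w[k + 1] * vk
  }
  res
}

# precompute everything that does not depend on (d, e)
.dec_engine <- function(tree, tips, space, rel_tol = 1e-6) {
  tree <- validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree has polytomies; resolve_polytomies() first")
  cu <- check_ultrametric(tree, rel_tol)
  if (!cu$ultrametric)
    stop(sprintf(
      "tree is not ultrametric (relative deviation %.3g); rescale with %s",
      cu$max_deviation, "strict_clock_chronogram()"))
  ntip <- ape::Ntip(tree)
  labs <- tree$tip.label
  if (!setequal(names(tips), labs))
    stop("tip states do not match tree tips; missing: ",
         paste(setdiff(labs, names(tips)), collapse = ", "),
         "; extra: ", paste(setdiff(names(tips), labs), collapse = ", "))
  tip_state <- .states_from_families(space, tips)[labs]

  pe <- ape::reorder.phylo(tree, "postorder")
  clado <- cladogenesis_table(space)
  # flat event vectors, sorted by parent so rowsum-style reduction is ordered
  o <- order(clado$parent)
  ev_parent <- clado$parent[o]
  ev_left <- clado$left[o]
  ev_right <- clado$right[o]
  ev_prob <- clado$prob[o]

  adj <- .dec_adjacency(space)
  children <- vector("list", ntip + tree$Nnode)
  edge_len <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(pe$edge))) {
    p <- pe$edge[k, 1]
    children[[p]] <- c(children[[p]], pe$edge[k, 2])
    edge_len[[p]] <- c(edge_len[[p]], pe$edge.length[k])
  }
  node_order <- unique(pe$edge[, 1]) # parents in postorder

  list(tree = tree, ntip = ntip, nnode = tree$Nnode, space = space,
       tip_state = tip_state, children = children, edge_len = edge_len,
       node_order = node_order, root = ntip + 1L,
       ev_parent = ev_parent, ev_left = ev_left, ev_right = ev_right,
       ev_prob = ev_prob, gain = adj$gain, loss = adj$loss)
}

# propagator for given rates: eigendecomposition when the state space is
# small enough for it to pay off (verified against the generator, falling
# back to uniformization if Q is numerically defective)
.dec_generator <- function(eng, d, e, eigen_cutoff = 200L) {
  n <- eng$space$n_states
  Qoff <- d * eng$gain + e * eng$loss
  rs <- Matrix::rowSums(Qoff)
  Omega <- max(rs)
  if (n <= eigen_cutoff && Omega > 0) {
    Q <- as.matrix(Qoff)
    diag(Q) <- diag(Q) - rs
    eg <- tryCatch(eigen(Q), error = function(e) NULL)
    if (!is.null(eg)) {
      Uinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
      if (!is.null(Uinv)) {
        err <- max(Mod(eg$vectors %*% (eg$values * Uinv) - Q))
        if (err < 1e-9 * max(1, Omega))
          return(list(type = "eigen", U = eg$vectors, lam = eg$values,
                      Uinv = Uinv))
      }
    }
  }
  M <- if (Omega > 0)
    (Qoff + Matrix::Diagonal(n, Omega - rs)) / Omega
  else Matrix::Diagonal(n)
  list(type = "unif", M = M, Omega = Omega)
}

# pruning pass; returns per-node combined partials L (scaled), the
# branch-propagated daughter partials D, log-scalers and the root logL
.dec_pruning <- function(eng, d, e, root_prior = "uniform",
                         keep_partials = FALSE) {
  gen <- .dec_generator(eng, d, e)
  n <- eng$space$n_states
  ntot <- eng$ntip + eng$nnode
  L <- vector("list", ntot)
  D <- if (keep_partials) vector("list", ntot) else NULL
  for (i in seq_len(eng$ntip)) {
    v <- numeric(n); v[eng$tip_state[i]] <- 1
    L[[i]] <- v
  }
  logscale <- 0
  for (v in eng$node_order) {
    ch <- eng$children[[v]]
    tl <- eng$edge_len[[v]]
    D1 <- .exp_action(gen, tl[1], L[[ch[1]]])
    D2 <- .exp_action(gen, tl[2], L[[ch[2]]])
    if (keep_partials) { D[[ch[1]]] <- D1; D[[ch[2]]] <- D2 }
    contrib <- eng$ev_prob * D1[eng$ev_left] * D2[eng$ev_right]
    Lv <- as.numeric(rowsum(contrib, eng$ev_parent, reorder = FALSE))
    sc <- max(Lv)
    if (sc <= 0) return(list(logL = -Inf))
    L[[v]] <- Lv / sc
    logscale <- logscale + log(sc)
  }
  Lroot <- L[[eng$root]]
  prior <- if (identical(root_prior, "uniform")) rep(1 / n, n)
           else Lroot / sum(Lroot) # FitzJohn-style likelihood weighting
  logL <- log(sum(prior * Lroot)) + logscale
  list(logL = logL, L = L, D = D, prior = prior, gen = gen)
}

#' DEC* log-likelihood
#'
#' Felsenstein pruning on an ultrametric binary tree: tip partials are
#' indicator vectors on the observed host-family ranges, internal nodes
#' combine daughter partials through the cladogenetic event table, branches
#' propagate by the anagenetic CTMC, and the root sums over states under
#' the chosen prior (uniform over all allowed states by default;
#' `"fitzjohn"` weights states by their conditional likelihood).
#'
#' @param tree ultrametric binary rooted `phylo` (checked at relative
#'   tolerance 1e-6).
#' @param tips named list (tip label -> character vector of families).
#' @param params a `dec_params`.
#' @param space a `range_state_space`.
#' @param root_prior `"uniform"` (default) or `"fitzjohn"`.
#' @return log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, tips, params, space, root_prior = "uniform") {
  stopifnot(inherits(params, "dec_params"))
  eng <- .dec_engine(tree, tips, space)
  .dec_pruning(eng, params$d, params$e, root_prior)$logL
}

#' Maximum-likelihood DEC* rates
#'
#' Bounded 2-D optimization of the log-likelihood over log(d), log(e) with
#' three deterministic starting points scaled to the tree height; the best
#' of the three local fits is returned and bound-touching estimates are
#' flagged, not rejected.
#'
#' @inheritParams dec_loglik
#' @param bounds numeric length-2: box for both rates (default 1e-9 to 10).
#' @return list with `params` (`dec_params`), `logL`, `bound_hit`
#'   (logical), `convergence` (optim codes per start), `starts`.
#' @export
fit_dec <- function(tree, tips, space, bounds = c(1e-9, 10),
                    root_prior = "uniform") {
  eng <- .dec_engine(tree, tips, space)
  h <- max(ape::node.depth.edgelength(eng$tree))
  starts <- list(c(0.02, 0.02) / h, c(0.2, 0.1) / h, c(2, 1) / h)
  starts <- lapply(starts, function(s) pmin(pmax(s, bounds[1]), bounds[2]))
  nll <- function(lp) {
    out <- .dec_pruning(eng, exp(lp[1]), exp(lp[2]), root_prior)$logL
    if (!is.finite(out)) return(1e10)
    -out
  }
  best <- NULL
  conv <- integer(length(starts))
  for (k in seq_along(starts)) {
    fit <- optim(log(starts[[k]]), nll, method = "L-BFGS-B",
                 lower = log(bounds[1]), upper = log(bounds[2]),
                 control = list(factr = 1e7))
    conv[k] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  d_hat <- exp(best$par[1]); e_hat <- exp(best$par[2])
  bound_hit <- any(abs(best$par - log(bounds[1])) < 1e-6) ||
    any(abs(best$par - log(bounds[2])) < 1e-6)
  if (bound_hit)
    .msg("fitted DEC* rate at a search bound (d = ",
         signif(d_hat, 3), ", e = ", signif(e_hat, 3), ")")
  list(params = dec_params(d_hat, e_hat), logL = -best$value,
       bound_hit = bound_hit, convergence = conv, starts = starts)
}

#' Marginal ancestral host ranges under DEC*
#'
#' Standard marginal reconstruction adapted to cladogenetic mixing: the
#' probability vector reported at each internal node is over its state just
#' before the cladogenetic split, combining the node's below-partials with
#' above-partials propagated from the rest of the tree. The most probable
#' state uses the lowest state index on exact ties.
#'
#' @inheritParams dec_loglik
#' @return object of class `ancestral_estimate`: `probs` (internal nodes x
#'   states matrix, rows summing to 1, rownames the ape node numbers),
#'   `map_state` (index) and `map_label` per node, `logL`, `params`,
#'   `space`.
#' @export
ancestral_states <- function(tree, tips, params, space,
                             root_prior = "uniform") {
  stopifnot(inherits(params, "dec_params"))
  eng <- .dec_engine(tree, tips, space)
  pr <- .dec_pruning(eng, params$d, params$e, root_prior,
                     keep_partials = TRUE)
  if (!is.finite(pr$logL)) stop("data have zero likelihood at these rates")
  n <- eng$space$n_states
  ntot <- eng$ntip + eng$nnode
  G <- vector("list", ntot)
  G[[eng$root]] <- pr$prior
  # preorder: reverse postorder of internal nodes
  for (v in rev(eng$node_order)) {
    ch <- eng$children[[v]]
    tl <- eng$edge_len[[v]]
    for (k in 1:2) {
      cx <- ch[k]; sib <- ch[3 - k]
      Dsib <- pr$D[[sib]]
      # the event table contains both daughter orders, so accumulating on
      # the 'left' slot with the sibling on 'right' covers either position
      contrib <- G[[v]][eng$ev_parent] * eng$ev_prob * Dsib[eng$ev_right]
      H <- numeric(n)
      agg <- rowsum(contrib, eng$ev_left)
      H[as.integer(rownames(agg))] <- agg
      Gc <- .exp_action(pr$gen, tl[k], H, transpose = TRUE)
      sc <- max(Gc)
      G[[cx]] <- if (sc > 0) Gc / sc else Gc
    }
  }
  nodes <- eng$ntip + seq_len(eng$nnode)
  probs <- matrix(0, eng$nnode, n,
                  dimnames = list(nodes, eng$space$labels))
  for (v in nodes) {
    m <- G[[v]] * pr$L[[v]]
    s <- sum(m)
    if (s <= 0) stop("zero marginal at node ", v)
    probs[as.character(v), ] <- m / s
  }
  map_state <- apply(probs, 1, which.max)
  structure(list(probs = probs, map_state = map_state,
                 map_label = eng$space$labels[map_state],
                 logL = pr$logL, params = params, space = space),
            class = "ancestral_estimate")
}

#' @export
print.ancestral_estimate <- function(x, ...) {
  cat(sprintf(
    "DEC* ancestral ranges: %d internal nodes, %d states (d = %.4g, e = %.4g, logL = %.4f)\n",
    nrow(x$probs), ncol(x$probs), x$params$d, x$params$e, x$logL))
  cat("Most probable root state:", x$map_label[1], "\n")
  invisible(x)
}
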