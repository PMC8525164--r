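## Tree data model: Newick I/O, patristic distances, phylogenetic covariance,
## strict-clock chronogram rescaling. Trees are ape "phylo" objects throughout;
## this file adds validation and the clock machinery on top of ape.

#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] with structural validation: balanced parentheses
#' (reported with the character offset of the first imbalance), unique
#' non-empty tip labels, and non-negative branch lengths. Branch lengths
#' missing from the input are set to 0 with a warning, which accommodates
#' mega-tree exports that omit inner edge lengths.
#'
#' @param text a Newick string (terminating `;`). Quoted labels are supported
#'   and square-bracket comments are ignored, as in ape's reader.
#' @return an object of class `phylo`.
#' @seealso [write_newick()], [patristic_distances()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("Newick parse error: reader returned no tree")
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths on output.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate a phylogeny for use in hostphylo
#'
#' Checks unique non-empty tip labels and non-negative branch lengths;
#' missing branch lengths become 0 with a warning.
#'
#' @param tree a `phylo` object.
#' @return the (possibly repaired) `phylo` object, invisibly validated.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("tree has empty tip labels")
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  tree
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips. For a
#' host chronogram in million years these are the phylogenetic distances
#' used by the host-sharing regression.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a symmetric numeric matrix with tips in `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic (Brownian-motion) covariance matrix
#'
#' `V[i, j]` is the shared root-to-tip path length, i.e. the depth of the
#' most recent common ancestor of tips i and j. Under Brownian motion the
#' trait covariance is proportional to this matrix.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return a symmetric numeric matrix, tips in `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  tree <- validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. ape::root) before computing V")
  v <- ape::vcv.phylo(tree)
  v[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Test whether a tree is ultrametric and report the deviation
#'
#' @param tree a rooted `phylo` object.
#' @param rel_tol relative tolerance on root-to-tip depth variation.
#' @return list with `ultrametric` (logical) and `max_deviation`
#'   (max over tips of |depth - mean depth| / mean depth).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  m <- mean(depths)
  dev <- if (m > 0) max(abs(depths - m)) / m else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

#' Resolve polytomies deterministically
#'
#' Breaks multifurcations into bifurcations with zero-length branches
#' (required by the DEC* engine, which assumes binary trees).
#'
#' @param tree a `phylo` object.
#' @return a binary `phylo` object.
#' @export
resolve_polytomies <- function(tree) {
  tree <- validate_tree(tree)
  if (ape::is.binary(tree)) return(tree)
  out <- ape::multi2di(tree, random = FALSE)
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

# ages of all nodes given per-internal-node fractions s in (0,1):
# age(root) = root_age, age(child) = age(parent) * s[child], tips at 0.
.ages_from_fractions <- function(tree, s, root_age, preorder) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  age <- numeric(ntip + nnode)
  root <- ntip + 1L
  age[root] <- root_age
  parent_of <- integer(ntip + nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (v in preorder) {
    if (v == root || v <= ntip) next
    age[v] <- age[parent_of[v]] * s[v - ntip]
  }
  age
}

#' Strict-clock chronogram by constrained least squares
#'
#' Rescales a phylogram to an ultrametric chronogram under a single global
#' rate: node ages and the rate r minimize
#' \eqn{\sum_b (\ell_b - r \, t_b)^2} over branches, where \eqn{\ell_b} is the
#' observed branch length and \eqn{t_b} the branch duration implied by the
#' ages, subject to every parent being older than its children. With equal
#' rates this is the deterministic equivalent of penalized-likelihood dating:
#' the smoothing penalty vanishes and ages are identified by branch-length
#' fit alone. Only relative ages are identified, so the root age is a free
#' scale (default 1).
#'
#' @param tree a rooted `phylo` with non-negative branch lengths.
#' @param root_age age assigned to the root (same units as desired output).
#' @param control list; `maxit` for the optimizer (default 500).
#' @return an ultrametric `phylo` with identical topology, plus attributes
#'   `rate` (fitted global rate) and `objective` (residual sum of squares).
#' @export
strict_clock_chronogram <- function(tree, root_age = 1, control = list()) {
  tree <- validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted for clock rescaling")
  stopifnot(is.numeric(root_age), root_age > 0)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  blen <- tree$edge.length

  # preorder of nodes (parents before children)
  po_edges <- ape::reorder.phylo(tree, "postorder")
  preorder <- rev(po_edges$edge[, 2])
  preorder <- c(root, preorder[preorder > ntip])

  # init ages proportional to the maximum tip distance below each node:
  # exact for trees already on a clock, a sensible start otherwise
  hts <- numeric(ntip + nnode)
  pe <- po_edges$edge
  pl <- po_edges$edge.length
  for (k in seq_len(nrow(pe))) {
    p <- pe[k, 1]; ch <- pe[k, 2]
    hts[p] <- max(hts[p], hts[ch] + pl[k])
  }
  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  s0 <- rep(0.5, nnode)
  for (v in preorder) {
    if (v == root) next
    num <- hts[v]; den <- hts[parent_of[v]]
    s0[v - ntip] <- if (den > 0) min(max(num / den, 0.01), 0.99) else 0.5
  }
  free <- setdiff(preorder, root) # internal non-root nodes
  par0 <- qlogis(s0[free - ntip])

  obj <- function(par) {
    s <- s0
    s[free - ntip] <- plogis(par)
    age <- .ages_from_fractions(tree, s, root_age, preorder)
    t_b <- age[edge[, 1]] - age[edge[, 2]]
    sst <- sum(t_b^2)
    r <- if (sst > 0) sum(blen * t_b) / sst else 0
    sum((blen - r * t_b)^2)
  }

  if (length(par0)) {
    fit <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = control$maxit %||% 500,
                                reltol = 1e-14))
    s <- s0
    s[free - ntip] <- plogis(fit$par)
    objective <- fit$value
  } else {
    s <- s0
    objective <- obj(numeric(0))
  }
  age <- .ages_from_fractions(tree, s, root_age, preorder)
  t_b <- age[edge[, 1]] - age[edge[, 2]]
  sst <- sum(t_b^2)
  out <- tree
  out$edge.length <- t_b
  attr(out, "rate") <- if (sst > 0) sum(blen * t_b) / sst else 0
  attr(out, "objective") <- objective
  out
}
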