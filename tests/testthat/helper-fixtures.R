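# Shared fixtures and independent oracles used across the suite.

# small association table built in code
toy_association_df <- function() {
  data.frame(
    fly_species = c("Fly a", "Fly a", "Fly a", "Fly b", "Fly b", "Fly c"),
    host_species = c("Cucumis sativus", "Cucumis melo", "Citrus limon",
                     "Cucumis sativus", "Citrus limon", "Cucumis melo"),
    host_genus = c("Cucumis", "Cucumis", "Citrus",
                   "Cucumis", "Citrus", "Cucumis"),
    host_family = c("Cucurbitaceae", "Cucurbitaceae", "Rutaceae",
                    "Cucurbitaceae", "Rutaceae", "Cucurbitaceae"),
    stringsAsFactors = FALSE)
}

# patristic distances by explicit root-to-tip path enumeration -- an oracle
# independent of the cophenetic-based implementation
oracle_patristic <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent_of <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- v
    while (parent_of[v] != 0) { v <- parent_of[v]; nodes <- c(nodes, v) }
    nodes
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    lca <- shared[1]
    climb <- function(v) { s <- 0
      while (v != lca) { s <- s + elen[v]; v <- parent_of[v] }; s }
    d[i, j] <- climb(i) + climb(j)
  }
  d
}

# brute-force DEC* log-likelihood and node marginals by explicit summation
# over all joint assignments of pre-split states to internal nodes
oracle_dec <- function(tree, tips, space, params, root_prior = "uniform") {
  ntip <- ape::Ntip(tree)
  ct <- cladogenesis_table(space)
  Q <- anagenetic_rate_matrix(space, params)
  pe <- ape::reorder.phylo(tree, "postorder")
  ch <- vector("list", ntip + tree$Nnode)
  el <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(pe$edge))) {
    p <- pe$edge[k, 1]
    ch[[p]] <- c(ch[[p]], pe$edge[k, 2])
    el[[p]] <- c(el[[p]], pe$edge.length[k])
  }
  tipidx <- hostphylo:::.states_from_families(space, tips)[tree$tip.label]
  internal <- ntip + seq_len(tree$Nnode)
  S <- space$n_states
  Pmats <- lapply(internal, function(v)
    lapply(1:2, function(k) transition_probabilities(Q, el[[v]][k])))
  names(Pmats) <- internal
  joint <- function(assign) {
    pr <- 1 / S
    for (vi in seq_along(internal)) {
      v <- internal[vi]
      evs <- ct[ct$parent == assign[vi], ]
      s <- 0
      for (r in seq_len(nrow(evs))) {
        term <- evs$prob[r]
        tops <- c(evs$left[r], evs$right[r])
        for (k in 1:2) {
          cx <- ch[[v]][k]
          P <- Pmats[[as.character(v)]][[k]]
          bottom <- if (cx <= ntip) tipidx[cx]
                    else assign[match(cx, internal)]
          term <- term * P[tops[k], bottom]
        }
        s <- s + term
      }
      pr <- pr * s
    }
    pr
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  total <- 0
  marg <- matrix(0, length(internal), S,
                 dimnames = list(internal, space$labels))
  for (rr in seq_len(nrow(grid))) {
    p <- joint(grid[rr, ])
    total <- total + p
    for (vi in seq_along(internal)) marg[vi, grid[rr, vi]] <-
      marg[vi, grid[rr, vi]] + p
  }
  list(logL = log(total), marg = marg / total)
}

# random ultrametric binary tree of unit height
random_chronogram <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}
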