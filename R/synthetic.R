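## Forward simulators with known ground truth: Yule trees, Brownian and
## lambda-attenuated tip traits, distance-decay fly-host association
## systems (the stand-in for a curated association database), and DEC*
## range histories. Same seed + parameters always reproduce the same
## output; every generator's product passes the corresponding module's
## input validation.

#' Simulate a Yule (pure-birth) tree
#'
#' Rooted, binary, ultrametric tree conditioned on the number of tips.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer seed.
#' @param tip_prefix prefix for tip labels (suffix is a zero-padded index).
#' @return a `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_prefix = "t") {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("%s%0*d", tip_prefix,
                          nchar(as.character(n_tips)), seq_len(n_tips))
  validate_tree(tr)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Tip values drawn from the multivariate normal with covariance
#' `variance_rate * V`, V the phylogenetic covariance of the tree.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param variance_rate Brownian rate (variance per unit branch length).
#' @param seed optional integer seed.
#' @return named numeric vector over the tips.
#' @export
simulate_bm_trait <- function(tree, variance_rate = 1, seed = NULL) {
  simulate_lambda_trait(tree, lam = 1, variance_rate = variance_rate,
                        seed = seed)
}

#' @rdname simulate_bm_trait
#' @param lam Pagel's lambda in \[0, 1\]; 1 recovers Brownian motion, 0 an
#'   independent (star-phylogeny) trait.
#' @export
simulate_lambda_trait <- function(tree, lam, variance_rate = 1, seed = NULL) {
  stopifnot(lam >= 0, lam <= 1, variance_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  V <- lambda_transform(phylo_covariance(tree), lam)
  y <- as.numeric(MASS::mvrnorm(1, mu = rep(0, nrow(V)),
                                Sigma = variance_rate * V))
  names(y) <- tree$tip.label
  y
}

# cut an ultrametric tree at the age where exactly n_groups lineages exist;
# returns integer group id per tip
.cut_tree_groups <- function(tree, n_groups) {
  ntip <- ape::Ntip(tree)
  if (n_groups > ntip) stop("cannot cut ", ntip, " tips into ", n_groups,
                            " groups")
  if (n_groups < 2) return(setNames(rep(1L, ntip), tree$tip.label))
  bt <- sort(ape::branching.times(tree), decreasing = TRUE)
  hi <- bt[n_groups - 1]
  lo <- if (length(bt) >= n_groups) bt[n_groups] else 0
  if (hi <= lo) stop("tied branching times prevent a clean cut")
  a <- (hi + lo) / 2
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ntip)]) - depth
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  grp <- integer(ntip)
  for (i in seq_len(ntip)) {
    v <- i
    while (age[parent_of[v]] < a) v <- parent_of[v]
    grp[i] <- v # the lineage crossing age a above tip i
  }
  setNames(match(grp, sort(unique(grp))), tree$tip.label)
}

#' Simulate a fly-host association system with distance-decay host use
#'
#' Builds a host-genus chronogram (Yule, rescaled to `host_root_age` Myr)
#' whose genera are grouped into families by cutting the tree at the age
#' where exactly `n_families` lineages exist; a fly phylogeny; and an
#' association table in which each fly receives a seed host genus and
#' attacks every other genus with probability
#' `plogis(beta0 + beta1 * log10(d + 1))`, d the patristic distance from
#' the seed in Myr. Attacked genera are expanded into species-level records
#' from per-genus species pools. An optional breadth profile pins the
#' number of monophagous flies (confined to the seed genus's family) and of
#' extreme polyphages (topped up with random additional families until they
#' reach a floor).
#'
#' @param n_flies,n_genera,n_families system dimensions.
#' @param beta0,beta1 intercept and slope of the attack-probability decay.
#' @param host_root_age root age of the host chronogram in Myr.
#' @param breadth_profile optional list with `n_monophages`, `n_extreme`,
#'   `extreme_min_families`.
#' @param species_rate mean number of extra species per genus (Poisson).
#' @param seed optional integer seed.
#' @return list with `table` (`association_table`), `host_tree`,
#'   `fly_tree`, and `truth` (class `synthetic_truth`: generator name,
#'   seed, true parameters, seed genera, per-fly class).
#' @export
simulate_association_system <- function(n_flies = 37, n_genera = 286,
                                        n_families = 87,
                                        beta0 = 1.7962, beta1 = -1.6633,
                                        host_root_age = 150,
                                        breadth_profile = NULL,
                                        species_rate = 1.5, seed = NULL) {
  stopifnot(n_flies >= 2, n_genera >= 4, n_families >= 1,
            n_families <= n_genera)
  if (!is.null(seed)) set.seed(seed)
  classes <- rep("typical", n_flies)
  if (!is.null(breadth_profile)) {
    nm <- breadth_profile$n_monophages %||% 0
    nx <- breadth_profile$n_extreme %||% 0
    xmin <- breadth_profile$extreme_min_families %||% 20
    if (nm + nx > n_flies)
      stop("breadth profile infeasible: ", nm, " + ", nx, " > ", n_flies)
    if (xmin > n_families)
      stop("breadth profile infeasible: extreme_min_families > n_families")
    classes[seq_len(nm)] <- "monophage"
    if (nx > 0) classes[nm + seq_len(nx)] <- "extreme"
  }

  host_tree <- simulate_yule_tree(n_genera, 1, tip_prefix = "Genus")
  host_tree$edge.length <- host_tree$edge.length *
    host_root_age / max(ape::node.depth.edgelength(host_tree))
  fam_id <- .cut_tree_groups(host_tree, n_families)
  fam_of <- sprintf("Fam%0*d", nchar(as.character(n_families)), fam_id)
  names(fam_of) <- names(fam_id)
  genera <- host_tree$tip.label
  n_sp <- 1L + rpois(n_genera, species_rate)
  names(n_sp) <- genera

  fly_tree <- simulate_yule_tree(n_flies, 1, tip_prefix = "Fly")
  flies <- fly_tree$tip.label
  classes <- setNames(classes, flies)
  D <- patristic_distances(host_tree)

  seed_genus <- setNames(sample(genera, n_flies, replace = TRUE), flies)
  recs <- list()
  for (f in flies) {
    src <- seed_genus[[f]]
    p <- plogis(beta0 + beta1 * log10(D[src, ] + 1))
    attacked <- genera[runif(n_genera) < p]
    attacked <- union(src, attacked)
    if (classes[[f]] == "monophage") {
      attacked <- attacked[fam_of[attacked] == fam_of[src]]
    } else if (classes[[f]] == "typical" && !is.null(breadth_profile)) {
      # intermediate class: family breadth stays below the extreme floor,
      # retaining the families phylogenetically closest to the seed
      xmin <- breadth_profile$extreme_min_families %||% 20
      have <- unique(fam_of[attacked])
      if (length(have) >= xmin) {
        target <- max(2L, min(xmin - 1L, 2L + rpois(1, 5)))
        fam_dist <- vapply(have, function(fm)
          min(D[src, attacked[fam_of[attacked] == fm]]), numeric(1))
        keep_fams <- have[order(fam_dist)][seq_len(target)]
        attacked <- attacked[fam_of[attacked] %in% keep_fams]
      }
    } else if (classes[[f]] == "extreme") {
      xmin <- breadth_profile$extreme_min_families %||% 20
      have <- unique(fam_of[attacked])
      pool <- genera[!(fam_of[genera] %in% have)]
      while (length(have) < xmin && length(pool)) {
        g <- sample(pool, 1)
        attacked <- c(attacked, g)
        have <- unique(fam_of[attacked])
        pool <- genera[!(fam_of[genera] %in% have)]
      }
    }
    for (g in attacked) {
      sp_pool <- sprintf("%s sp%d", g, seq_len(n_sp[[g]]))
      take <- sp_pool[runif(length(sp_pool)) < 0.6]
      if (!length(take)) take <- sample(sp_pool, 1)
      recs[[length(recs) + 1L]] <- data.frame(
        fly_species = f, host_species = take, host_genus = g,
        host_family = fam_of[[g]], stringsAsFactors = FALSE)
    }
  }
  table <- association_table(do.call(rbind, recs))
  truth <- structure(list(
    generator = "simulate_association_system", seed = seed,
    beta0 = beta0, beta1 = beta1, host_root_age = host_root_age,
    seed_genus = as.list(seed_genus), class = as.list(classes),
    genus_family = as.list(fam_of),
    n_records = nrow(table), n_flies = n_flies, n_genera = n_genera,
    n_families_drawn = length(unique(fam_of))),
    class = "synthetic_truth")
  list(table = table, host_tree = host_tree, fly_tree = fly_tree,
       truth = truth)
}

#' Forward-simulate a DEC* range history
#'
#' Exact stochastic simulation of the DEC* process on a binary ultrametric
#' tree: the root range is drawn uniformly from the state space, each
#' branch evolves by a Gillespie jump process with per-family dispersal
#' rate `d` (while below the size cap) and extirpation rate `e` (while the
#' range has >= 2 families), and each internal node splits by an event
#' drawn from the cladogenesis table. True states are recorded at every
#' node just before its split.
#'
#' @param tree binary ultrametric rooted `phylo`.
#' @param space a `range_state_space`.
#' @param params a `dec_params`.
#' @param seed optional integer seed.
#' @return list with `tip_states` (named list of family vectors),
#'   `node_state` (integer state index per internal ape node number, the
#'   pre-split state), `root_state`.
#' @export
simulate_dec_history <- function(tree, space, params, seed = NULL) {
  stopifnot(inherits(space, "range_state_space"),
            inherits(params, "dec_params"))
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree must be rooted and binary")
  if (!check_ultrametric(tree, 1e-6)$ultrametric)
    stop("tree must be ultrametric")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nf <- length(space$families)
  clado <- cladogenesis_table(space)
  ev_by_parent <- split(clado, clado$parent)

  evolve <- function(set, t) {
    repeat {
      gains <- if (length(set) < space$max_size)
        setdiff(seq_len(nf), set) else integer(0)
      losses <- if (length(set) >= 2) set else integer(0)
      rate <- params$d * length(gains) + params$e * length(losses)
      if (rate == 0) return(set)
      dt <- rexp(1, rate)
      if (dt > t) return(set)
      t <- t - dt
      if (runif(1) < params$d * length(gains) / rate) {
        set <- sort(c(set, if (length(gains) == 1) gains
                      else sample(gains, 1)))
      } else {
        drop <- if (length(losses) == 1) losses else sample(losses, 1)
        set <- setdiff(set, drop)
      }
    }
  }
  set_to_index <- function(set)
    as.integer(space$index_of_mask[[as.character(sum(2^(set - 1)))]])

  pe <- ape::reorder.phylo(tree, "postorder")
  node_seq <- c(ntip + 1L, rev(unique(pe$edge[, 1])))
  node_seq <- unique(node_seq) # root first, preorder
  children <- vector("list", ntip + tree$Nnode)
  edge_len <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(pe$edge))) {
    p <- pe$edge[k, 1]
    children[[p]] <- c(children[[p]], pe$edge[k, 2])
    edge_len[[p]] <- c(edge_len[[p]], pe$edge.length[k])
  }

  state_at <- vector("list", ntip + tree$Nnode) # pre-split / tip sets
  root <- ntip + 1L
  state_at[[root]] <- space$sets[[sample(space$n_states, 1)]]
  node_state <- integer(tree$Nnode)
  names(node_state) <- as.character(ntip + seq_len(tree$Nnode))
  for (v in node_seq) {
    set <- state_at[[v]]
    node_state[[as.character(v)]] <- set_to_index(set)
    ev <- ev_by_parent[[as.character(set_to_index(set))]]
    pick <- ev[sample(nrow(ev), 1, prob = ev$prob), ]
    tops <- list(space$sets[[pick$left]], space$sets[[pick$right]])
    ch <- children[[v]]
    for (k in 1:2) {
      end <- evolve(tops[[k]], edge_len[[v]][k])
      state_at[[ch[k]]] <- end
    }
  }
  tip_states <- lapply(seq_len(ntip), function(i)
    space$families[state_at[[i]]])
  names(tip_states) <- tree$tip.label
  list(tip_states = tip_states, node_state = node_state,
       root_state = node_state[[as.character(root)]])
}
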