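## DEC* model components: the subset state space over host families (null
## range disallowed), the anagenetic dispersal/extirpation rate matrix, the
## cladogenetic event table (subset sympatry + vicariance, uniform over
## distinct ordered daughter pairs), and CTMC transition probabilities.

#' Build the DEC* range state space
#'
#' All non-empty subsets of the family list up to `max_size`, ordered by
#' size then lexicographically by family position. The empty range is
#' excluded throughout (DEC*), so a single-family range cannot be
#' extirpated. The family count is capped at 12 (4095 states) because the
#' likelihood cost grows with the square of the state count.
#'
#' @param families character vector of range units (host families).
#' @param max_size maximum range size (default: all families).
#' @return object of class `range_state_space`: list with `families`,
#'   `max_size`, `sets` (integer index vectors), `masks` (bitmask per
#'   state), `labels`, `n_states`, `index_of_mask` (named lookup).
#' @export
build_state_space <- function(families, max_size = length(families)) {
  stopifnot(is.character(families), !anyDuplicated(families))
  nf <- length(families)
  if (nf < 1) stop("need at least one family")
  if (nf > 12)
    stop("state space for ", nf, " families would contain up to ",
         format(2^nf - 1, big.mark = ","),
         " states; restrict to at most 12 families")
  if (max_size < 1 || max_size > nf)
    stop("max_size must lie in [1, ", nf, "]")
  sets <- list()
  for (k in seq_len(max_size)) {
    cmb <- utils::combn(nf, k)
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  masks <- vapply(sets, function(s) sum(2^(s - 1)), numeric(1))
  labels <- vapply(sets, function(s) paste(families[s], collapse = "+"),
                   character(1))
  idx <- seq_along(sets)
  names(idx) <- as.character(masks)
  structure(list(families = families, max_size = max_size, sets = sets,
                 masks = masks, labels = labels, n_states = length(sets),
                 index_of_mask = idx),
            class = "range_state_space")
}

#' DEC* rate parameters
#' @param d dispersal (family gain) rate, per family per unit time.
#' @param e extirpation (family loss) rate, per family per unit time.
#' @return object of class `dec_params`.
#' @export
dec_params <- function(d, e) {
  stopifnot(is.numeric(d), is.numeric(e), length(d) == 1, length(e) == 1,
            is.finite(d), is.finite(e), d >= 0, e >= 0)
  structure(list(d = d, e = e), class = "dec_params")
}

# sparse 0/1 adjacency of dispersal (gain) and extirpation (loss) moves;
# Q(d, e) = d * gain + e * loss - diag(row sums)
.dec_adjacency <- function(space) {
  n <- space$n_states
  nf <- length(space$families)
  gi <- gj <- li <- lj <- integer(0)
  for (i in seq_len(n)) {
    s <- space$sets[[i]]
    if (length(s) < space$max_size) {
      for (f in setdiff(seq_len(nf), s)) {
        j <- space$index_of_mask[[as.character(space$masks[i] + 2^(f - 1))]]
        gi <- c(gi, i); gj <- c(gj, j)
      }
    }
    if (length(s) >= 2) {
      for (f in s) {
        j <- space$index_of_mask[[as.character(space$masks[i] - 2^(f - 1))]]
        li <- c(li, i); lj <- c(lj, j)
      }
    }
  }
  list(gain = Matrix::sparseMatrix(i = gi, j = gj, x = 1, dims = c(n, n)),
       loss = Matrix::sparseMatrix(i = li, j = lj, x = 1, dims = c(n, n)))
}

#' Anagenetic DEC* rate matrix
#'
#' Off-diagonal rates: `d` from a range to each one-family superset within
#' the size cap, `e` from a range of size >= 2 to each one-family subset.
#' Single-family ranges have no loss moves (no null range under DEC*).
#' Rows sum to zero.
#'
#' @param space a `range_state_space`.
#' @param params a `dec_params`.
#' @return dense square rate matrix with state labels as dimnames.
#' @export
anagenetic_rate_matrix <- function(space, params) {
  stopifnot(inherits(space, "range_state_space"),
            inherits(params, "dec_params"))
  adj <- .dec_adjacency(space)
  Q <- as.matrix(params$d * adj$gain + params$e * adj$loss)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(space$labels, space$labels)
  Q
}

#' CTMC transition probability matrix
#'
#' Matrix exponential P = exp(Q t). Entries within -1e-12 of zero are
#' clamped to 0; rows are verified to sum to 1 within 1e-10.
#'
#' @param Q a valid rate matrix (rows summing to 0).
#' @param t elapsed time, >= 0.
#' @return stochastic matrix of the same dimension.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("t must be a single non-negative number")
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t, sparse = FALSE)))
  neg <- P < 0
  if (any(P[neg] < -1e-12))
    stop("matrix exponential produced negative entries beyond tolerance")
  if (any(neg)) P[neg] <- 0
  if (max(abs(rowSums(P) - 1)) > 1e-10)
    stop("matrix exponential rows do not sum to 1; invalid generator?")
  dimnames(P) <- dimnames(Q)
  P
}

#' Cladogenetic event table
#'
#' For a single-family parent range the range is inherited identically by
#' both daughters. For larger ranges the allowed events are subset sympatry
#' (one daughter a single constituent family, the other the full parent
#' range) and vicariance (one daughter a single family, the other the
#' remainder), in both daughter orders; duplicate ordered pairs are merged
#' and probability is uniform over the distinct pairs. Widespread full
#' sympatry and founder-event (jump) dispersal are excluded, matching plain
#' DEC without the +J parameter.
#'
#' @param space a `range_state_space`.
#' @return data.frame of class `clado_table` with integer state-index
#'   columns `parent`, `left`, `right` and `prob`; per-parent probabilities
#'   sum to 1. State labels are available via `space$labels`.
#' @export
cladogenesis_table <- function(space) {
  stopifnot(inherits(space, "range_state_space"))
  rows <- vector("list", space$n_states)
  for (i in seq_len(space$n_states)) {
    s <- space$sets[[i]]
    if (length(s) == 1L) {
      rows[[i]] <- data.frame(parent = i, left = i, right = i, prob = 1)
      next
    }
    pairs <- matrix(integer(0), ncol = 2)
    for (f in s) {
      fi <- space$index_of_mask[[as.character(2^(f - 1))]]
      rest <- space$index_of_mask[[as.character(space$masks[i] - 2^(f - 1))]]
      pairs <- rbind(pairs,
                     c(fi, i), c(i, fi),       # subset sympatry
                     c(fi, rest), c(rest, fi)) # vicariance
    }
    pairs <- unique(pairs)
    rows[[i]] <- data.frame(parent = i, left = pairs[, 1], right = pairs[, 2],
                            prob = 1 / nrow(pairs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("clado_table", "data.frame")
  attr(out, "space") <- space
  out
}

# map a list of family-name vectors to state indices in the space
.states_from_families <- function(space, tips) {
  vapply(names(tips), function(nm) {
    fams <- tips[[nm]]
    if (!length(fams)) stop("empty range for '", nm,
                            "': null states are disallowed")
    pos <- match(fams, space$families)
    if (anyNA(pos))
      stop("unknown family for '", nm, "': ",
           paste(fams[is.na(pos)], collapse = ", "))
    mask <- sum(2^(unique(pos) - 1))
    i <- space$index_of_mask[as.character(mask)]
    if (is.na(i))
      stop("range of '", nm, "' exceeds max_size ", space$max_size)
    as.integer(i)
  }, integer(1))
}
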