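#' Extract the extant phylogeny from the species table
#'
#' Builds the rooted binary tree over exactly the species extant at
#' `at_time` from the simulator's birth/death records.  Internal nodes are
#' the speciation events with at least two surviving descendant lineages;
#' lineages with a single surviving descendant are suppressed (unary
#' chains collapse), so every internal node is a bifurcation.  Branch
#' lengths are elapsed simulation steps and the tree is ultrametric: every
#' tip sits at `at_time`.  Simultaneous daughters of one parent are
#' resolved in species-id order (earlier id closer to the root), giving
#' zero-length internal branches rather than polytomies.  The stem below
#' the first surviving split is not represented (the root node is the
#' first bifurcation).
#'
#' @param species Data frame with columns `species_id`, `parent_id`,
#'   `origin_time`, `extinction_time` (NA while extant), as in
#'   `simulation_result$species`.  Ids must be 1..n in birth order, with
#'   `parent_id` NA only for the root.
#' @param at_time Observation step; a species is extant at `at_time` if it
#'   originated at or before `at_time` and its extinction time is NA or
#'   later than `at_time`.
#' @return An [ape::phylo] tree; tip labels are the species ids.
#' @export
extant_tree <- function(species, at_time) {
  n_sp <- nrow(species)
  id <- species$species_id
  if (!identical(as.integer(id), seq_len(n_sp))) {
    stop("species table must have species_id 1..n in order")
  }
  par <- species$parent_id
  b <- species$origin_time
  d <- species$extinction_time
  extant <- b <= at_time & (is.na(d) | d > at_time)
  if (sum(extant) < 2L) {
    stop("fewer than 2 species extant at time ", at_time,
         "; no informative tree")
  }
  born <- b <= at_time
  # survivor = has >= 1 extant descendant lineage (incl. itself)
  surv <- extant & born
  for (s in n_sp:2L) if (surv[s] && born[s]) surv[par[s]] <- TRUE
  surv <- surv & born

  n_tip <- sum(extant)
  tip_of <- integer(n_sp)                  # species id -> tip number
  tip_of[extant] <- seq_len(n_tip)
  max_nodes <- n_tip - 1L
  node_time <- numeric(max_nodes)
  node_kid1 <- integer(max_nodes)          # >0 internal node, <0 tip number
  node_kid2 <- integer(max_nodes)
  n_node <- 0L

  # surviving children of each surviving species, ordered by (birth, id)
  kids <- vector("list", n_sp)
  surv_ids <- which(surv)
  ch <- surv_ids[!is.na(par[surv_ids])]
  if (length(ch)) {
    o <- order(par[ch], b[ch], ch)
    kids_split <- split(ch[o], par[ch][o])
    kids[as.integer(names(kids_split))] <- kids_split
  }

  handle_elem <- integer(n_sp)             # subtree handle per species
  handle_time <- numeric(n_sp)
  for (s in rev(surv_ids)) {
    if (extant[s]) {
      cur_elem <- -tip_of[s]
      cur_time <- at_time
      have <- TRUE
    } else {
      have <- FALSE
      cur_elem <- 0L; cur_time <- 0
    }
    ks <- kids[[s]]
    if (length(ks)) {
      for (c_id in rev(ks)) {              # latest-born merges first
        if (!have) {
          cur_elem <- handle_elem[c_id]
          cur_time <- handle_time[c_id]
          have <- TRUE
        } else {
          n_node <- n_node + 1L
          node_time[n_node] <- b[c_id]
          node_kid1[n_node] <- handle_elem[c_id]
          node_kid2[n_node] <- cur_elem
          cur_elem <- n_node
          cur_time <- b[c_id]
        }
      }
    }
    handle_elem[s] <- cur_elem
    handle_time[s] <- cur_time
  }

  root_elem <- handle_elem[which(surv)[1L]]  # lowest surviving id = root line
  if (root_elem < 0L) stop("internal error: degenerate tree")
  # preorder renumber: tips 1..n_tip, internal nodes n_tip+1 .. 2*n_tip-1
  n_edge <- 2L * (n_tip - 1L)
  edge <- matrix(0L, n_edge, 2L)
  edge_len <- numeric(n_edge)
  newnum <- integer(max_nodes)
  stack <- integer(max_nodes + 1L)
  stack[1L] <- root_elem
  top <- 1L
  next_node <- n_tip + 1L
  e <- 0L
  newnum[root_elem] <- next_node
  next_node <- next_node + 1L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    for (kid in c(node_kid1[v], node_kid2[v])) {
      e <- e + 1L
      edge[e, 1L] <- newnum[v]
      if (kid < 0L) {
        edge[e, 2L] <- -kid
        edge_len[e] <- at_time - node_time[v]
      } else {
        newnum[kid] <- next_node
        edge[e, 2L] <- next_node
        next_node <- next_node + 1L
        edge_len[e] <- node_time[kid] - node_time[v]
        top <- top + 1L
        stack[top] <- kid
      }
    }
  }
  tr <- list(
    edge = edge,
    edge.length = edge_len,
    tip.label = as.character(which(extant)),
    Nnode = n_tip - 1L
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Serialize a tree to Newick text
#'
#' Standard Newick with branch lengths (via [ape::write.tree]); tip labels
#' are the bare species ids.  `ape::read.tree(text = to_newick(tr))`
#' reproduces the topology and branch lengths.
#'
#' @param tree An [ape::phylo] tree.
#' @return A single Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Root distances (node depth) of every tip
#'
#' For each tip, the number of internal nodes on the path from the root to
#' that tip, counting the root as 1: both tips of a two-tip tree have root
#' distance 1.  The mean over the species of a region, scaled by the
#' maximum root distance of the tree, is the scaled mean root distance
#' (MRD) used by [mrd_richness_slope()].
#'
#' @param tree An [ape::phylo] tree with >= 2 tips.
#' @return Named integer vector (names = tip labels).
#' @export
root_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("root distances need >= 2 tips")
  tr <- ape::reorder.phylo(tree, "cladewise")
  depth <- integer(n_tip + tr$Nnode)
  root <- n_tip + 1L
  depth[root] <- 1L
  edge <- tr$edge                  # cladewise: a node's in-edge precedes
  for (e in seq_len(nrow(edge))) { # its out-edges
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + 1L
  }
  rd <- depth[seq_len(n_tip)] - 1L   # tip depth minus itself = internal count
  names(rd) <- tree$tip.label
  rd
}

# (left, right) descendant-tip counts of every internal node
.split_sizes <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_all <- n_tip + tr$Nnode
  cnt <- integer(n_all)
  cnt[seq_len(n_tip)] <- 1L
  k1 <- integer(n_all); k2 <- integer(n_all)
  edge <- tr$edge                  # postorder: child subtrees complete
  for (e in seq_len(nrow(edge))) { # before the edge into their parent
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    cnt[p] <- cnt[p] + cnt[ch]
    if (k1[p] == 0L) k1[p] <- ch else k2[p] <- ch
  }
  nodes <- (n_tip + 1L):n_all
  cbind(left = cnt[k1[nodes]], right = cnt[k2[nodes]])
}

# log-likelihood of Aldous' beta-splitting model for a set of (i, n-i)
# splits; q_n(i; beta) proportional to
# Gamma(beta+i+1) Gamma(beta+n-i+1) / (Gamma(i+1) Gamma(n-i+1)),
# normalized over i = 1..n-1.  Splits with n = 2 carry no information.
.beta_loglik <- function(beta, splits) {
  i <- splits[, 1L]
  n <- splits[, 1L] + splits[, 2L]
  keep <- n >= 3L
  if (!any(keep)) return(0)
  i <- i[keep]; n <- n[keep]
  term <- lgamma(beta + i + 1) + lgamma(beta + n - i + 1) -
    lgamma(i + 1) - lgamma(n - i + 1)
  logZ <- vapply(unique(n), function(nn) {
    ii <- seq_len(nn - 1L)
    x <- lgamma(beta + ii + 1) + lgamma(beta + nn - ii + 1) -
      lgamma(ii + 1) - lgamma(nn - ii + 1)
    m <- max(x)
    m + log(sum(exp(x - m)))
  }, numeric(1))
  names(logZ) <- unique(n)
  sum(term) - sum(logZ[as.character(n)])
}

#' Maximum-likelihood estimate of beta-splitting tree imbalance
#'
#' Aldous' beta-splitting model assigns to each internal node with `n >= 3`
#' descendant tips a probability of splitting into `(i, n - i)` tips
#' proportional to
#' `Gamma(beta+i+1) Gamma(beta+n-i+1) / (Gamma(i+1) Gamma(n-i+1))`,
#' normalized over `i = 1..n-1`.  `beta = 0` corresponds to the Yule
#' model; negative values mean more imbalanced (caterpillar-like) trees,
#' with the fully imbalanced limit at the lower boundary, and positive
#' values more balanced trees.  The log-likelihood is maximized over
#' `beta` in \[-2, 10\] by Brent/golden-section search; a maximum at
#' either end of the range is returned as the boundary value with
#' attribute `boundary = TRUE`.  The estimate depends only on the
#' topology, so it is invariant to rescaling branch lengths.
#'
#' @param tree An [ape::phylo] tree with >= 3 tips.
#' @param lower,upper Search range for beta.
#' @return The ML estimate (numeric scalar) with attributes `loglik` (the
#'   maximized log-likelihood) and `boundary` (logical).
#' @export
beta_ml <- function(tree, lower = -2, upper = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) {
    stop("beta estimation needs >= 3 tips (one informative split)")
  }
  splits <- .split_sizes(tree)
  if (!any(splits[, 1L] + splits[, 2L] >= 3L)) {
    stop("no informative split (all internal nodes subtend 2 tips)")
  }
  eps <- 1e-5
  opt <- optimize(.beta_loglik, interval = c(lower + eps, upper),
                  splits = splits, maximum = TRUE, tol = 1e-6)
  est <- opt$maximum
  ll <- opt$objective
  boundary <- FALSE
  # Brent can stall an interval-width away from a boundary optimum
  ll_lo <- .beta_loglik(lower + eps, splits)
  ll_hi <- .beta_loglik(upper, splits)
  if (ll_lo >= ll - 1e-9 && est - (lower + eps) < 0.01) {
    est <- lower; ll <- ll_lo; boundary <- TRUE
  } else if (ll_hi >= ll - 1e-9 && upper - est < 0.01) {
    est <- upper; ll <- ll_hi; boundary <- TRUE
  }
  structure(est, loglik = ll, boundary = boundary)
}

#' Equal-splits (DR) tip speciation-rate statistic
#'
#' For tip i with branch lengths `l_1` (pendant), `l_2`, ... `l_d` along
#' the path to the root, the equal-splits measure is
#' `ES_i = sum_j l_j * 2^-(j-1)` and the tip rate is `1 / ES_i`.  Faster
#' recent branching (short root-ward branches) gives larger rates; the
#' statistic uses the phylogeny only, so it applies to externally supplied
#' trees as well as simulated ones.
#'
#' @param tree An ultrametric [ape::phylo] tree with >= 2 tips.
#' @return Named numeric vector of per-step rates (names = tip labels).
#' @export
equal_splits_rate <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("equal-splits rates need >= 2 tips")
  n_all <- n_tip + tree$Nnode
  parent <- integer(n_all)
  plen <- numeric(n_all)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  root <- n_tip + 1L
  es <- numeric(n_tip)
  for (tip in seq_len(n_tip)) {
    v <- tip
    w <- 1
    acc <- 0
    while (v != root) {
      acc <- acc + plen[v] * w
      w <- w / 2
      v <- parent[v]
    }
    es[tip] <- acc
  }
  if (any(es <= 0)) stop("zero total path length; rate undefined")
  setNames(1 / es, tree$tip.label)
}

#' Realized per-lineage speciation rate of one tip
#'
#' The ground-truth analog of a tip speciation rate: the number of
#' speciation events on the root-to-tip lineage path recorded in the event
#' log, divided by the elapsed time from the clade origin to `at_time`.
#' An event lies on the path if its parent species is an ancestor of the
#' tip and it occurred while the path ran along that ancestor (between the
#' ancestor's own birth and the branching point toward the tip);
#' simultaneous same-parent events are ordered by child id, matching the
#' binary resolution used by [extant_tree()].
#'
#' @param species Species table (see [extant_tree()]).
#' @param events Event log data frame with columns `time`, `type`,
#'   `species_id`, `child_id`.
#' @param tip Species id of an extant tip.
#' @param at_time Observation step (> root origin time).
#' @return Rate per step (numeric scalar).
#' @export
lineage_event_rate <- function(species, events, tip, at_time) {
  b <- species$origin_time
  par <- species$parent_id
  root_t <- b[which(is.na(par))[1L]]
  if (at_time <= root_t) stop("zero elapsed time; rate undefined")
  spec <- events[events$type == "speciation" & events$time <= at_time, ,
                 drop = FALSE]
  # ancestor chain root -> tip
  chain <- tip
  v <- tip
  while (!is.na(par[v])) { v <- par[v]; chain <- c(v, chain) }
  count <- 0L
  for (j in seq_along(chain)) {
    s <- chain[j]
    ev <- spec[spec$species_id == s, , drop = FALSE]
    if (nrow(ev) == 0L) next
    lo <- b[s]
    if (j < length(chain)) {
      nxt <- chain[j + 1L]
      on_path <- ev$time > lo & (ev$time < b[nxt] |
        (ev$time == b[nxt] & ev$child_id <= nxt))
    } else {
      on_path <- ev$time > lo & ev$time <= at_time
    }
    count <- count + sum(on_path)
  }
  count / (at_time - root_t)
}

# vectorized realized rates for all extant tips at `at_time`
# g(s) = branching events on the path root -> birth of s
.realized_tip_rates <- function(species, events, at_time) {
  b <- species$origin_time
  par <- species$parent_id
  n_sp <- nrow(species)
  root_t <- b[which(is.na(par))[1L]]
  spec <- events[events$type == "speciation" & events$time <= at_time, ,
                 drop = FALSE]
  ev_by_parent <- split(seq_len(nrow(spec)), spec$species_id)
  g <- numeric(n_sp)
  own_upto <- function(s, t_hi, tie_child = NA) {
    idx <- ev_by_parent[[as.character(s)]]
    if (is.null(idx)) return(0L)
    tm <- spec$time[idx]
    n <- sum(tm > b[s] & tm < t_hi)
    if (!is.na(tie_child)) {
      n <- n + sum(tm == t_hi & spec$child_id[idx] <= tie_child)
    }
    n
  }
  for (s in seq_len(n_sp)) {
    p <- par[s]
    if (is.na(p)) { g[s] <- 0; next }
    g[s] <- g[p] + own_upto(p, b[s], tie_child = s)
  }
  extant <- b <= at_time &
    (is.na(species$extinction_time) | species$extinction_time > at_time)
  ids <- which(extant)
  counts <- vapply(ids, function(s) {
    idx <- ev_by_parent[[as.character(s)]]
    own <- if (is.null(idx)) 0L else {
      tm <- spec$time[idx]
      sum(tm > b[s] & tm <= at_time)
    }
    g[s] + own
  }, numeric(1))
  setNames(counts / (at_time - root_t), as.character(ids))
}
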