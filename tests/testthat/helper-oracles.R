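# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each statistic from its textbook definition
# and never call the package functions they are checking.

# Pearson correlation from the raw definition
pearson_direct <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# OLS slope of y on x from the normal equations
ols_slope_direct <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# (left, right) tip counts of each internal node, via ape's clade partitions
split_sizes_via_ape <- function(tree) {
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  clade_size <- function(v) if (v <= n_tip) 1L else length(pp[[v - n_tip]])
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  t(vapply(nodes, function(v) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    c(clade_size(kids[1L]), clade_size(kids[2L]))
  }, integer(2)))
}

# beta-splitting log-likelihood evaluated directly from the split
# probability product (normalization by explicit summation)
beta_loglik_direct <- function(tree, beta) {
  ss <- split_sizes_via_ape(tree)
  ll <- 0
  for (r in seq_len(nrow(ss))) {
    n <- ss[r, 1L] + ss[r, 2L]
    if (n < 3L) next
    f <- function(i) exp(lgamma(beta + i + 1) + lgamma(beta + n - i + 1) -
                           lgamma(i + 1) - lgamma(n - i + 1))
    ll <- ll + log(f(ss[r, 1L]) / sum(vapply(1:(n - 1L), f, numeric(1))))
  }
  ll
}

# brute-force grid maximum of the beta-splitting log-likelihood
beta_grid_max <- function(tree, grid = seq(-1.99, 10, by = 0.01)) {
  ll <- vapply(grid, function(b) beta_loglik_direct(tree, b), numeric(1))
  list(beta = grid[which.max(ll)], loglik = max(ll))
}

# all unlabeled binary tree shapes with n tips, as Newick strings
tree_shapes <- local({
  memo <- list("1" = "x")
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- character()
    for (i in seq_len(n %/% 2)) {
      left <- tree_shapes(i)
      right <- tree_shapes(n - i)
      for (a in seq_along(left)) {
        bs <- if (i == n - i) a:length(right) else seq_along(right)
        for (b in bs) {
          out <- c(out, paste0("(", left[a], ",", right[b], ")"))
        }
      }
    }
    memo[[key]] <<- out
    out
  }
})

# label the x placeholders t1, t2, ... and parse
shape_to_phylo <- function(shape) {
  n <- lengths(regmatches(shape, gregexpr("x", shape)))
  for (i in seq_len(n)) shape <- sub("x", paste0("t", i), shape)
  ape::read.tree(text = paste0(shape, ";"))
}

caterpillar_newick <- function(n) {
  s <- paste0("(t1:1,t2:1)")
  for (i in 3:n) s <- paste0("(", s, ":1,t", i, ":", i - 1, ")")
  paste0(s, ";")
}

# fully balanced tree with n_tips = 2^k tips, unit branch lengths
balanced_phylo <- function(n_tips) {
  s <- "x"
  tips <- 1L
  while (tips < n_tips) {
    s <- paste0("(", s, ":1,", s, ":1)")
    tips <- tips * 2L
  }
  for (i in seq_len(n_tips)) s <- sub("x", paste0("t", i), s)
  ape::read.tree(text = paste0(s, ";"))
}

# fabricate a sim_state holding n independent species with given traits,
# home regions and populations (field surgery on the documented state env)
fab_state <- function(cfg, traits, regions, pops, t = 1L) {
  S <- new_sim_state(cfg)
  n <- length(traits)
  R <- cfg$n_regions
  S$cap <- n
  S$n_sp <- n
  S$trait <- as.numeric(traits)
  S$parent <- c(NA_integer_, rep(1L, n - 1L))
  S$origin_t <- rep(0L, n)
  S$extinct_t <- rep(NA_integer_, n)
  S$alive <- rep(TRUE, n)
  S$resident <- matrix(FALSE, n, R)
  S$resident[cbind(seq_len(n), regions)] <- TRUE
  S$pop <- matrix(0, n, R)
  S$pop[cbind(seq_len(n), regions)] <- pops
  S$col_t <- matrix(NA_real_, n, R)
  S$col_t[cbind(seq_len(n), regions)] <- 0
  S$act <- seq_len(n)
  S$t <- t
  S
}
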