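# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force enumeration for the Mk
# likelihood and marginals, direct pair counting for the rank-sum statistic,
# closed-form 2-state transition probabilities, and a numerically optimised
# Firth logistic regression.

# Exhaustive Mk likelihood: sum over every internal-node state assignment of
# prior x product of per-edge transition probabilities.
brute_mk_loglik <- function(tree, states, Q, prior = NULL) {
  lev <- rownames(Q)
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  po <- reorder(tree, "postorder")
  E <- po$edge
  P <- lapply(po$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  N <- ape::Ntip(tree)
  M <- tree$Nnode
  tipidx <- match(as.character(states[tree$tip.label]), lev)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), M)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asn <- c(tipidx, grid[r, ])
    pr <- prior[asn[N + 1L]]
    for (e in seq_len(nrow(E))) pr <- pr * P[[e]][asn[E[e, 1]], asn[E[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# Exhaustive marginal ancestral probabilities from the same joint enumeration.
brute_marginal <- function(tree, states, Q, prior = NULL) {
  lev <- rownames(Q)
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  po <- reorder(tree, "postorder")
  E <- po$edge
  P <- lapply(po$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  N <- ape::Ntip(tree)
  M <- tree$Nnode
  tipidx <- match(as.character(states[tree$tip.label]), lev)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), M)))
  marg <- matrix(0, M, k)
  for (r in seq_len(nrow(grid))) {
    asn <- c(tipidx, grid[r, ])
    pr <- prior[asn[N + 1L]]
    for (e in seq_len(nrow(E))) pr <- pr * P[[e]][asn[E[e, 1]], asn[E[e, 2]]]
    for (v in seq_len(M)) marg[v, grid[r, v]] <- marg[v, grid[r, v]] + pr
  }
  marg / rowSums(marg)
}

# 2-state equal-rates transition probability, closed form.
p2_stay <- function(q, t) 0.5 + 0.5 * exp(-2 * q * t)

# Rank-sum U statistic of group 1 by direct pair counting (ties count 1/2).
count_pairs_W <- function(g1, g2) {
  s <- 0
  for (a in g1) for (b in g2) s <- s + (a > b) + 0.5 * (a == b)
  s
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments
# (no-ties case, small n).
exact_mw_p <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(x), n1)
  Wobs <- count_pairs_W(g1, g2)
  Wall <- apply(idx, 2, function(i) count_pairs_W(x[i], x[-i]))
  n <- length(Wall)
  mu <- n1 * length(g2) / 2
  mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-12)
}

# Firth-penalized logistic regression by direct numerical optimisation of the
# penalized log-likelihood (independent of the package's Newton/GEE path).
firth_logistic_oracle <- function(X, y) {
  pll <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    W <- p * (1 - p)
    -(sum(y * log(p) + (1 - y) * log(1 - p)) +
        0.5 * determinant(crossprod(X * sqrt(W)))$modulus)
  }
  stats::optim(numeric(ncol(X)), pll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$par
}

# Random rooted tree with branch lengths for property tests.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Random valid rate matrix.
random_q <- function(k, scale = 1) {
  lev <- letters[seq_len(k)]
  r <- stats::runif(k * (k - 1), 0.1, 1) * scale
  mk_q(r, lev, "ARD")
}
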