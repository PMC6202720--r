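# Mk model of discrete character evolution: rate matrices, transition
# probabilities, the pruning likelihood, maximum-likelihood fitting and
# marginal ancestral state reconstruction.

#' Build an Mk rate matrix
#'
#' Constructs a k x k instantaneous rate matrix from its off-diagonal rates.
#' `ER` has a single rate shared by all transitions, `SYM` one rate per
#' unordered state pair, `ARD` one per ordered pair. Rows sum to zero.
#'
#' @param rates numeric vector: length 1 (ER), k(k-1)/2 (SYM, filling the upper
#'   triangle column-wise and mirrored), or k(k-1) (ARD, row-wise
#'   off-diagonals).
#' @param state_names character vector of state names (defines k).
#' @param model one of `"ER"`, `"SYM"`, `"ARD"`.
#' @return Rate matrix with `state_names` dimnames and attribute
#'   `model_class`.
#' @export
mk_q <- function(rates, state_names, model = c("ER", "SYM", "ARD")) {
  model <- match.arg(model)
  if (any(rates < 0)) stop("negative transition rates", call. = FALSE)
  k <- length(state_names)
  if (k < 2L) stop("need at least 2 states", call. = FALSE)
  Q <- matrix(0, k, k, dimnames = list(state_names, state_names))
  if (model == "ER") {
    stopifnot(length(rates) == 1L)
    Q[] <- rates
  } else if (model == "SYM") {
    stopifnot(length(rates) == k * (k - 1) / 2)
    Q[upper.tri(Q)] <- rates  # column-wise upper triangle
    Q <- Q + t(Q)
  } else {
    stopifnot(length(rates) == k * (k - 1))
    idx <- which(t(row(Q) != col(Q)))  # row-wise off-diagonals
    tQ <- t(Q); tQ[idx] <- rates; Q <- t(tQ)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  attr(Q, "model_class") <- model
  Q
}

validate_q <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square", call. = FALSE)
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12))
    stop("invalid rate matrix: negative off-diagonal rates", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-8))
    stop("invalid rate matrix: rows must sum to zero", call. = FALSE)
  Q
}

# Transition-probability factory: returns function(t) -> P(t) = expm(Q t).
# Uses the eigendecomposition when the eigenvector basis is well conditioned
# (one decomposition, cheap per-branch evaluation), otherwise falls back to
# Matrix::expm. Rows are clamped to [0, 1] and renormalised against round-off.
make_tprob <- function(Q) {
  Q <- unclass(validate_q(Q))
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    kap <- tryCatch(kappa(eg$vectors, exact = FALSE), error = function(e) Inf)
    use_eigen <- is.finite(kap) && kap < 1e8
  }
  if (use_eigen) {
    Vi <- solve(eg$vectors)
    V <- eg$vectors
    lam <- eg$values
    function(t) {
      if (t == 0) return(diag(k))
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      if (t == 0) return(diag(k))
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

resolve_root_prior <- function(root_prior, Q, down_root = NULL) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("equal", "stationary", "estimated")),
    equal = rep(1 / k, k),
    stationary = {
      # left null vector of Q: pi Q = 0
      e <- eigen(t(Q))
      i <- which.min(abs(e$values))
      p <- abs(Re(e$vectors[, i]))
      p / sum(p)
    },
    estimated = {
      if (is.null(down_root)) stop("no root partials available", call. = FALSE)
      down_root / sum(down_root)
    })
}

# Core pruning engine shared by the likelihood, the marginal reconstruction
# and the stochastic-map sampler. Computes, in post-order, the per-node
# partial likelihoods D (rescaled rows; log scale factors tracked) and the
# per-edge arrays B[e, s] = sum_{s'} P_e[s, s'] D_child(s').
mk_engine <- function(tree, states, Q, root_prior = "equal") {
  bound <- bind_traits(tree, states, state_names = rownames(Q) %||% NULL)
  tree <- bound$tree
  st <- bound$states
  Q <- validate_q(Q)
  k <- nrow(Q)
  if (nlevels(st) != k)
    stop("state set (", nlevels(st), ") does not match Q dimension (", k, ")",
         call. = FALSE)
  lev <- levels(st)
  if (!is.null(rownames(Q)) && !identical(rownames(Q), lev))
    stop("Q dimnames must match state names ", paste(lev, collapse = ", "),
         call. = FALSE)

  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  el <- po$edge.length
  N <- ape::Ntip(tree)
  M <- tree$Nnode
  tp <- make_tprob(Q)
  P <- lapply(el, tp)

  down <- matrix(1, N + M, k)
  down[cbind(seq_len(N), as.integer(st))] <- 1
  down[seq_len(N), ] <- 0
  down[cbind(seq_len(N), as.integer(st))] <- 1
  logsc <- numeric(N + M)
  B <- matrix(0, nrow(E), k)

  for (e in seq_len(nrow(E))) {
    par <- E[e, 1]; ch <- E[e, 2]
    b <- as.vector(P[[e]] %*% down[ch, ])
    B[e, ] <- b
    down[par, ] <- down[par, ] * b
    logsc[par] <- logsc[par] + logsc[ch]
    m <- max(down[par, ])
    if (m <= 0) {
      logsc[par] <- -Inf
    } else {
      down[par, ] <- down[par, ] / m
      logsc[par] <- logsc[par] + log(m)
    }
  }
  root <- N + 1L
  prior <- resolve_root_prior(root_prior, Q, down_root = down[root, ])
  list(tree = tree, states = st, Q = Q, levels = lev, edge = E,
       edge.length = el, P = P, down = down, logsc = logsc, B = B,
       ntip = N, nnode = M, root = root, prior = prior, tprob = tp)
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Log of the probability of the observed tip states summed over all internal
#' state assignments, computed by Felsenstein's post-order pruning with
#' per-branch transition matrices `P(t) = expm(Q t)` and per-node rescaling for
#' numerical stability.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param states named vector of tip states (see [bind_traits()]).
#' @param Q rate matrix (see [mk_q()]); dimnames, if present, must match the
#'   state names.
#' @param root_prior `"equal"` (default), `"stationary"`, `"estimated"`
#'   (proportional to the root partial likelihoods), or a numeric vector.
#' @return Log-likelihood scalar.
#' @export
mk_loglik <- function(tree, states, Q, root_prior = "equal") {
  en <- mk_engine(tree, states, Q, root_prior)
  L <- sum(en$prior * en$down[en$root, ])
  if (L <= 0 || !is.finite(en$logsc[en$root])) return(-Inf)
  log(L) + en$logsc[en$root]
}

#' Fit an Mk model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over the transition rates of the
#' chosen model class, on the log-rate scale. The documented starting point is
#' one expected transition per state per total tree length
#' (`k / sum(edge.length)`); ER uses Brent search on a bracketed interval,
#' SYM/ARD use L-BFGS-B. Deterministic given inputs.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` (default, a single symmetric rate — the conventional
#'   choice for a 3-state character on a ~60-tip tree), `"SYM"` or `"ARD"`.
#' @param state_names optional full state set (needed when some states are
#'   unobserved at the tips).
#' @return List of class `"mk_fit"`: `Q`, `rates`, `loglik`, `model`,
#'   `convergence`, `boundary` (TRUE when the rate ran to the lower search
#'   bound, e.g. for an invariant character).
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM", "ARD"),
                   root_prior = "equal", state_names = NULL) {
  model <- match.arg(model)
  bound <- bind_traits(tree, states, state_names = state_names)
  tree <- bound$tree; st <- bound$states
  lev <- levels(st)
  k <- length(lev)
  tl <- sum(tree$edge.length)
  if (tl <= 0) stop("tree has zero total length", call. = FALSE)
  npar <- switch(model, ER = 1L, SYM = k * (k - 1L) %/% 2L, ARD = k * (k - 1L))
  lo <- log(1e-9); hi <- log(1e4 / tl)
  start <- rep(log(k / tl), npar)

  nll <- function(lp) {
    Q <- mk_q(exp(pmin(pmax(lp, lo), hi)), lev, model)
    -mk_loglik(tree, st, Q, root_prior)
  }

  if (npar == 1L) {
    opt <- stats::optimize(nll, interval = c(lo, hi), tol = 1e-8)
    lp <- opt$minimum; val <- opt$objective; conv <- 0L
  } else {
    opt <- stats::optim(start, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 500L))
    lp <- opt$par; val <- opt$value; conv <- opt$convergence
    if (conv != 0L)
      warning("optimizer did not converge (code ", conv,
              "); returning best point found", call. = FALSE)
  }
  rates <- exp(lp)
  boundary <- any(lp < lo + 0.5)
  if (boundary && length(unique(st)) == 1L)
    warning("character is invariant: rate estimate at lower boundary",
            call. = FALSE)
  structure(list(Q = mk_q(rates, lev, model), rates = rates,
                 loglik = -val, model = model, convergence = conv,
                 boundary = boundary, state_names = lev,
                 root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit (%s), %d states, logLik = %.4f\n",
              x$model, length(x$state_names), x$loglik))
  cat("rates:", signif(x$rates, 4), "\n")
  invisible(x)
}

#' Marginal ancestral state probabilities
#'
#' Per-node marginal posterior probabilities of each state under the Mk model,
#' from combined post-order (partial likelihoods) and pre-order (outside
#' likelihoods) passes. The root vector is proportional to the prior times the
#' root partial likelihoods; tips are unit vectors at their observed states.
#'
#' @inheritParams mk_loglik
#' @return Matrix of class `"ancestral_recon"`, rows = nodes (ape numbering:
#'   tips `1..N`, root `N+1`), columns = states; each row sums to 1.
#' @export
marginal_ancestral <- function(tree, states, Q, root_prior = "equal") {
  en <- mk_engine(tree, states, Q, root_prior)
  E <- en$edge; k <- length(en$levels)
  nn <- en$ntip + en$nnode
  children <- split(seq_len(nrow(E)), E[, 1])

  up <- matrix(0, nn, k)
  up[en$root, ] <- en$prior
  # pre-order = reverse post-order
  for (e in rev(seq_len(nrow(E)))) {
    par <- E[e, 1]; ch <- E[e, 2]
    m <- up[par, ]
    for (e2 in children[[as.character(par)]])
      if (e2 != e) m <- m * en$B[e2, ]
    u <- as.vector(t(en$P[[e]]) %*% m)
    s <- sum(u)
    up[ch, ] <- if (s > 0) u / s else u
  }
  post <- up * en$down
  rs <- rowSums(post)
  rs[rs == 0] <- 1
  post <- post / rs
  dimnames(post) <- list(NULL, en$levels)
  structure(post, class = c("ancestral_recon", "matrix"))
}
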