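# Stochastic character mapping: sampling full character histories along every
# branch conditional on tip data and Q, counting independent origins of
# states, and summarising node-state frequencies.

# Simulate one endpoint-conditioned CTMC path of length t from state `a` to
# state `b` by rejection sampling. When a != b the path is conditioned on at
# least one change by drawing the first event time from the exponential
# truncated to [0, t]. Returns a named numeric vector of dwell lengths whose
# names are state names, ordered rootward -> tipward.
sim_branch_history <- function(a, b, t, Q, lev, max_attempts = 1e6) {
  k <- nrow(Q)
  if (t <= 0) {
    if (a != b) stop("zero-length branch with differing endpoint states",
                     call. = FALSE)
    return(stats::setNames(0, lev[a]))
  }
  for (att in seq_len(max_attempts)) {
    s <- a
    times <- numeric(0)
    states <- integer(0)
    now <- 0
    first <- TRUE
    repeat {
      r <- -Q[s, s]
      if (r <= 0) break  # absorbing state: dwells forever
      if (first && a != b) {
        # condition on >= 1 change: truncated exponential on [0, t]
        u <- stats::runif(1)
        dt <- -log(1 - u * (1 - exp(-r * t))) / r
      } else {
        dt <- stats::rexp(1, r)
      }
      first <- FALSE
      if (now + dt >= t) break
      now <- now + dt
      p <- Q[s, ]; p[s] <- 0
      ns <- sample.int(k, 1L, prob = p)
      times <- c(times, now)
      states <- c(states, s)
      s <- ns
    }
    if (s == b) {
      bounds <- c(0, times, t)
      seq_states <- c(states, s)
      return(stats::setNames(diff(bounds), lev[seq_states]))
    }
  }
  stop("rejection sampling failed after ", max_attempts,
       " attempts on a branch of length ", signif(t, 4),
       "; consider a larger rate/branch tolerance", call. = FALSE)
}

#' Sample stochastic character maps
#'
#' Draws complete character histories conditional on the tip states and the
#' rate matrix: node states are sampled pre-order from their conditional
#' distributions (using the pruning partial likelihoods), then each branch
#' history is sampled conditional on its endpoint states by rejection sampling
#' of the continuous-time Markov chain. Node-state frequencies across many
#' maps approximate the marginal ancestral probabilities.
#'
#' @inheritParams mk_loglik
#' @param nsim number of maps (default 2000, at which node-state frequencies
#'   of a variable character have stabilised).
#' @param seed optional integer seed for reproducibility.
#' @param max_attempts rejection-sampling cap per branch (default 1e6).
#' @return List of class `"stochastic_maps"`; each element has `node_states`
#'   (named by ape node number) and `histories` (per postorder edge, a named
#'   vector of dwell lengths summing to the branch length). Attributes carry
#'   the tree, edge matrix and state names.
#' @export
sample_maps <- function(tree, states, Q, root_prior = "equal", nsim = 2000L,
                        seed = NULL, max_attempts = 1e6) {
  stopifnot(nsim >= 1L)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  en <- mk_engine(tree, states, Q, root_prior)
  E <- en$edge; k <- length(en$levels)
  nn <- en$ntip + en$nnode
  Qm <- unclass(en$Q)
  pre <- rev(seq_len(nrow(E)))

  maps <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    ns <- integer(nn)
    w <- en$prior * en$down[en$root, ]
    ns[en$root] <- sample.int(k, 1L, prob = w)
    hist <- vector("list", nrow(E))
    for (e in pre) {
      par <- E[e, 1]; ch <- E[e, 2]
      w <- en$P[[e]][ns[par], ] * en$down[ch, ]
      ns[ch] <- sample.int(k, 1L, prob = w)
      hist[[e]] <- sim_branch_history(ns[par], ns[ch], en$edge.length[e],
                                      Qm, en$levels, max_attempts)
    }
    maps[[i]] <- list(node_states = stats::setNames(en$levels[ns], seq_len(nn)),
                      histories = hist)
  }
  structure(maps, class = "stochastic_maps", tree = en$tree, edge = E,
            edge.length = en$edge.length, state_names = en$levels)
}

#' Count independent origins of a state
#'
#' For each sampled map, counts the transitions into the target state (segment
#' boundaries where the chain enters the state from a different one). By
#' default a root already in the target state counts as one origin, so the
#' count is the number of independent evolutionary gains visible on the map.
#'
#' @param maps a `"stochastic_maps"` object from [sample_maps()].
#' @param target_state state name of interest.
#' @param count_root should a root in the target state count as an origin?
#'   (default `TRUE`).
#' @return List of class `"origin_count"`: `counts` (per map), `modal_count`,
#'   `distribution` (table of counts).
#' @export
count_origins <- function(maps, target_state, count_root = TRUE) {
  stopifnot(inherits(maps, "stochastic_maps"), length(maps) >= 1L)
  lev <- attr(maps, "state_names")
  if (!target_state %in% lev)
    stop("unknown state: ", target_state, call. = FALSE)
  root <- ape::Ntip(attr(maps, "tree")) + 1L
  counts <- vapply(maps, function(m) {
    n <- if (count_root && m$node_states[[root]] == target_state) 1L else 0L
    for (h in m$histories) {
      s <- names(h)
      if (length(s) > 1L)
        n <- n + sum(s[-1L] == target_state & s[-length(s)] != target_state)
    }
    n
  }, integer(1))
  tab <- table(counts)
  structure(list(counts = counts,
                 modal_count = as.integer(names(tab)[which.max(tab)]),
                 distribution = tab, state = target_state),
            class = "origin_count")
}

#' @export
print.origin_count <- function(x, ...) {
  cat(sprintf("independent origins of '%s': modal count %d over %d maps\n",
              x$state, x$modal_count, length(x$counts)))
  print(x$distribution)
  invisible(x)
}

#' Node-state frequencies across stochastic maps
#'
#' Empirical per-node state frequencies across sampled maps — the values shown
#' as pie charts at internal nodes of a character-mapped tree. Converges to
#' [marginal_ancestral()] as the number of maps grows.
#'
#' @param maps a `"stochastic_maps"` object.
#' @return Matrix of class `"ancestral_recon"`, rows = nodes, columns =
#'   states; rows sum to 1.
#' @export
node_state_summary <- function(maps) {
  stopifnot(inherits(maps, "stochastic_maps"), length(maps) >= 1L)
  lev <- attr(maps, "state_names")
  nn <- length(maps[[1]]$node_states)
  freq <- matrix(0, nn, length(lev), dimnames = list(NULL, lev))
  for (m in maps) {
    idx <- match(m$node_states, lev)
    freq[cbind(seq_len(nn), idx)] <- freq[cbind(seq_len(nn), idx)] + 1
  }
  structure(freq / length(maps), class = c("ancestral_recon", "matrix"))
}

#' Expand a map's branch histories into a segment table
#'
#' @param maps a `"stochastic_maps"` object.
#' @param which_map index of the map to tabulate (default 1).
#' @return Data frame: `edge` (postorder index), `parent`, `child`, `segment`,
#'   `state`, `length`.
#' @export
map_segments <- function(maps, which_map = 1L) {
  m <- maps[[which_map]]
  E <- attr(maps, "edge")
  out <- lapply(seq_along(m$histories), function(e) {
    h <- m$histories[[e]]
    data.frame(edge = e, parent = E[e, 1], child = E[e, 2],
               segment = seq_along(h), state = names(h), length = unname(h))
  })
  do.call(rbind, out)
}

#' Simulate a discrete character along a tree (unconditioned)
#'
#' Forward simulation of the Mk process from a root state down every branch.
#' Used by the synthetic-data generator and for parameter-recovery tests; the
#' true per-branch histories are returned so generated gains are known.
#'
#' @inheritParams mk_loglik
#' @param root_state state name to start from; if `NULL`, drawn from
#'   `root_prior`.
#' @param seed optional seed.
#' @return Named factor of tip states with attributes `node_states`,
#'   `histories` (per postorder edge) and `n_transitions` (total state
#'   changes).
#' @export
sim_mk <- function(tree, Q, root_prior = "equal", root_state = NULL,
                   seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  tree <- validate_tree(tree)
  Q <- validate_q(Q)
  lev <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  k <- nrow(Q)
  po <- stats::reorder(tree, "postorder")
  E <- po$edge; el <- po$edge.length
  N <- ape::Ntip(tree); nn <- N + tree$Nnode
  prior <- resolve_root_prior(root_prior, Q)
  ns <- integer(nn)
  ns[N + 1L] <- if (is.null(root_state)) sample.int(k, 1L, prob = prior) else {
    i <- match(root_state, lev)
    if (is.na(i)) stop("unknown root state", call. = FALSE)
    i
  }
  hist <- vector("list", nrow(E))
  ntrans <- 0L
  Qm <- unclass(Q)
  for (e in rev(seq_len(nrow(E)))) {
    a <- ns[E[e, 1]]
    t <- el[e]
    s <- a; now <- 0
    times <- numeric(0); sts <- integer(0)
    repeat {
      r <- -Qm[s, s]
      if (r <= 0) break
      dt <- stats::rexp(1, r)
      if (now + dt >= t) break
      now <- now + dt
      p <- Qm[s, ]; p[s] <- 0
      times <- c(times, now); sts <- c(sts, s)
      s <- sample.int(k, 1L, prob = p)
    }
    ns[E[e, 2]] <- s
    hist[[e]] <- stats::setNames(diff(c(0, times, t)), lev[c(sts, s)])
    ntrans <- ntrans + length(times)
  }
  tips <- factor(stats::setNames(lev[ns[seq_len(N)]], tree$tip.label),
                 levels = lev)
  attr(tips, "node_states") <- stats::setNames(lev[ns], seq_len(nn))
  attr(tips, "histories") <- hist
  attr(tips, "edge") <- E
  attr(tips, "n_transitions") <- ntrans
  tips
}
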