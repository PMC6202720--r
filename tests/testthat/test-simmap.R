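# Stochastic character mapping: history validity, Monte-Carlo consistency
# with analytic marginals, and origin counting.

test_that("zero-length trees yield transition-free, tip-consistent maps", {
  tr <- read_tree("((A:0,B:0):0,C:0);")
  st <- c(A = "a", B = "a", C = "a")
  Q <- mk_q(0.5, c("a", "b"), "ER")
  maps <- sample_maps(tr, st, Q, nsim = 10, seed = 1)
  for (m in maps) {
    expect_true(all(m$node_states == "a"))
    expect_true(all(vapply(m$histories, length, 1L) == 1L))
  }
})

test_that("sampled histories conserve branch lengths and endpoint continuity", {
  set.seed(41)
  tr <- random_tree(10)
  Q <- mk_q(0.8, c("a", "b", "c"), "ER")
  st <- setNames(sample(c("a", "b", "c"), 10, TRUE), tr$tip.label)
  maps <- sample_maps(tr, st, Q, nsim = 50, seed = 42)
  E <- attr(maps, "edge")
  el <- attr(maps, "edge.length")
  for (m in maps[1:20]) {
    for (e in seq_len(nrow(E))) {
      h <- m$histories[[e]]
      expect_equal(sum(h), el[e], tolerance = 1e-9)
      # branch starts at the parent's sampled state, ends at the child's
      expect_identical(names(h)[1], unname(m$node_states[E[e, 1]]))
      expect_identical(names(h)[length(h)], unname(m$node_states[E[e, 2]]))
      if (length(h) > 1)  # adjacent segments must change state
        expect_true(all(names(h)[-1] != names(h)[-length(h)]))
    }
    # tip states agree with the data
    expect_identical(unname(m$node_states[1:10]), unname(st[tr$tip.label]))
  }
})

test_that("unconditional branch simulation has the Poisson change rate", {
  q <- 0.6; t <- 1.5
  tr <- read_tree(sprintf("(A:%f,B:%f);", t, t))
  Q <- mk_q(q, c("a", "b"), "ER")
  set.seed(43)
  nsim <- 2000
  changes <- replicate(nsim, {
    x <- sim_mk(tr, Q, root_state = "a")
    h <- attr(x, "histories")[[1]]  # one branch of length t
    length(h) - 1L
  })
  mu <- mean(changes)
  se <- sd(changes) / sqrt(nsim)
  expect_lt(abs(mu - q * t), 3 * se + 1e-12)
})

test_that("node-state frequencies converge to the analytic marginals", {
  set.seed(47)
  tr <- random_tree(8)
  Q <- mk_q(0.7, c("a", "b"), "ER")
  st <- setNames(sample(c("a", "b"), 8, TRUE), tr$tip.label)
  nsim <- 600
  maps <- sample_maps(tr, st, Q, nsim = nsim, seed = 48)
  freq <- node_state_summary(maps)
  ma <- marginal_ancestral(tr, st, Q)
  se <- sqrt(unclass(ma) * (1 - unclass(ma)) / nsim)
  expect_true(all(abs(freq - ma) <= 3 * se + 1e-9))
  expect_equal(unname(rowSums(freq)), rep(1, nrow(freq)))
})

test_that("origin counting matches hand-built and seeded ground truth", {
  # hand-built fixture: two independent gains of state b
  tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = "b", B = "a", C = "b", D = "a")
  Q <- mk_q(0.3, c("a", "b"), "ER")
  maps <- sample_maps(tr, st, Q, nsim = 1, seed = 5)
  fake <- maps
  E <- attr(maps, "edge")
  ns <- setNames(rep("a", 7), 1:7)
  ns[c("1", "3")] <- "b"  # tips A and C carry the derived state
  hist <- lapply(seq_len(nrow(E)), function(e) {
    par <- as.character(E[e, 1]); ch <- as.character(E[e, 2])
    if (ns[par] == ns[ch]) setNames(attr(maps, "edge.length")[e], ns[par])
    else setNames(c(0.5, 0.5) * attr(maps, "edge.length")[e],
                  c(ns[par], ns[ch]))
  })
  fake[[1]] <- list(node_states = ns, histories = hist)
  expect_equal(count_origins(fake, "b")$modal_count, 2L)
  expect_equal(count_origins(fake, "b", count_root = FALSE)$modal_count, 2L)

  # no target-state segments at all -> zero origins
  allsame <- fake
  allsame[[1]]$node_states[] <- "a"
  allsame[[1]]$histories <- lapply(seq_len(nrow(E)), function(e)
    setNames(attr(maps, "edge.length")[e], "a"))
  expect_equal(count_origins(allsame, "b")$modal_count, 0L)
  # a root already in the target state counts as one origin
  rootb <- allsame
  rootb[[1]]$node_states[] <- "b"
  rootb[[1]]$histories <- lapply(seq_len(nrow(E)), function(e)
    setNames(attr(maps, "edge.length")[e], "b"))
  expect_equal(count_origins(rootb, "b")$modal_count, 1L)
  expect_equal(count_origins(rootb, "b", count_root = FALSE)$modal_count, 0L)

  expect_error(count_origins(fake, "z"), "unknown state")
})

test_that("irreversible gains are recovered at their seeded count", {
  # three separated clades fixed in the derived state; gains cannot be lost
  tr <- read_tree(paste0("(((A:1,B:1):1,(C:1,D:1):1):1,",
                         "((E:1,F:1):1,(G:1,H:1):1):1);"))
  st <- c(A = "g", B = "g", C = "w", D = "w", E = "g", F = "g",
          G = "w", H = "g")
  # gain-only process: w -> g slowly, no reversal
  Q <- mk_q(c(0.15, 0), c("w", "g"), "ARD")
  maps <- sample_maps(tr, st, Q, root_prior = c(1, 0), nsim = 400, seed = 7)
  oc <- count_origins(maps, "g")
  expect_equal(oc$modal_count, 3L)
})

test_that("map segment tables tile each branch exactly", {
  set.seed(53)
  tr <- random_tree(6)
  Q <- mk_q(1.2, c("a", "b"), "ER")
  st <- setNames(sample(c("a", "b"), 6, TRUE), tr$tip.label)
  maps <- sample_maps(tr, st, Q, nsim = 3, seed = 54)
  seg <- map_segments(maps, 2L)
  lens <- tapply(seg$length, seg$edge, sum)
  expect_equal(as.numeric(lens), unname(attr(maps, "edge.length")),
               tolerance = 1e-9)
})

test_that("all-identical maps give unit-vector node summaries", {
  tr <- read_tree("((A:0,B:0):0,C:0);")
  st <- c(A = "b", B = "b", C = "b")
  maps <- sample_maps(tr, st, mk_q(0.4, c("a", "b"), "ER"), nsim = 25,
                      seed = 9)
  ns <- node_state_summary(maps)
  expect_true(all(ns %in% c(0, 1)))
  expect_true(all(ns[, "b"] == 1))
})
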