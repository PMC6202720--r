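# Synthetic data with known ground truth: birth-death trees, correlated
# binary host characters, host-driven defense phenotypes per lifestage, and
# colour scenes whose palettes follow the strategy.

#' Synthetic-study configuration
#'
#' Defaults emulate the structure of the empirical study system: 63
#' representative tips, host toxicity evolving as a slow binary Markov
#' character (a handful of host shifts across the tree), vegetation density
#' strongly concordant with toxicity (target correlation 0.9, i.e. ~5% of tips
#' flipped), a latitude-like distribution label, and host-predicted defense
#' phenotypes with a 5% exception rate (the occasional lineage that breaks the
#' host rule).
#'
#' @param n_tips number of tips (default 63).
#' @param birth_rate,death_rate per-lineage birth-death rates (defaults 1.0
#'   and 0.3; the tree is rescaled to height 1, so only their ratio shapes the
#'   branching times).
#' @param toxicity_rate symmetric switch rate of host toxicity per unit tree
#'   height (default 0.5, giving several independent host shifts on a
#'   height-1 tree, matching a radiation with repeated shifts between host
#'   classes).
#' @param host_correlation target correlation between toxicity and vegetation
#'   (default 0.9); vegetation is toxicity flipped per tip with probability
#'   `(1 - host_correlation) / 2`.
#' @param epsilon probability that a tip deviates from the host-predicted
#'   phenotype (default 0.05).
#' @param q_defense 3-state rate matrix used when simulating a *neutral*
#'   defense character (null simulations); default ER with rate 0.5.
#' @param seed integer seed; with the seed fixed all generated artefacts are
#'   byte-identical across runs.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_tips = 63L, birth_rate = 1.0, death_rate = 0.3,
                         toxicity_rate = 0.5, host_correlation = 0.9,
                         epsilon = 0.05, q_defense = NULL, seed = 1L) {
  stopifnot(n_tips >= 2L, birth_rate > death_rate, death_rate >= 0,
            toxicity_rate >= 0, host_correlation >= 0, host_correlation <= 1,
            epsilon >= 0, epsilon <= 1)
  structure(list(
    n_tips = as.integer(n_tips), birth_rate = birth_rate,
    death_rate = death_rate, toxicity_rate = toxicity_rate,
    host_correlation = host_correlation, epsilon = epsilon,
    q_defense = q_defense %||%
      mk_q(0.5, c("aposematism", "crypsis", "masquerade"), "ER"),
    seed = as.integer(seed)), class = "synth_config")
}

#' Simulate a birth-death tree rescaled to unit height
#'
#' @param config a [synth_config()].
#' @param seed optional override of `config$seed`.
#' @return A rooted bifurcating `phylo` with height 1.
#' @export
gen_tree <- function(config = synth_config(), seed = NULL) {
  old <- local_seed(seed %||% config$seed)
  on.exit(restore_seed(old), add = TRUE)
  tr <- ape::rphylo(config$n_tips, birth = config$birth_rate,
                    death = config$death_rate)
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_tips))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr
}

#' Simulate host-plant characters
#'
#' Toxicity evolves as a symmetric 2-state Markov character along the tree (so
#' host shifts are clade-structured, as in real host-plant evolution); the
#' history is redrawn until each host type covers at least 15% of the tips
#' *and* toxic feeding has arisen at least three times independently,
#' emulating a radiation in which both host classes are well represented and
#' host shifts recurred across lineages. Vegetation density copies toxicity
#' (toxic hosts are sparsely vegetated)
#' and is then flipped independently per tip with probability
#' `(1 - host_correlation) / 2`. The distribution label thresholds a
#' latitude-like Brownian value into temperate / tropical / both. Host plant
#' family names are drawn consistently with toxicity.
#'
#' @param tree a `phylo` object (typically from [gen_tree()]).
#' @param config a [synth_config()].
#' @param seed optional override seed.
#' @return Data frame (`species`, `family`, `toxicity`, `vegetation`,
#'   `distribution`) with attribute `truth`: the true toxicity histories and
#'   the number of independent toxicity gains (transitions into `"toxic"`,
#'   root included if toxic).
#' @export
sim_host_traits <- function(tree, config = synth_config(), seed = NULL) {
  old <- local_seed((seed %||% config$seed) + 1L)
  on.exit(restore_seed(old), add = TRUE)
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  Qt <- mk_q(config$toxicity_rate, c("nontoxic", "toxic"), "ER")
  count_gains <- function(tox) {
    # independent toxicity gains on the simulated history (root included)
    g <- if (attr(tox, "node_states")[[n + 1L]] == "toxic") 1L else 0L
    for (h in attr(tox, "histories")) {
      s <- names(h)
      if (length(s) > 1L)
        g <- g + sum(s[-1L] == "toxic" & s[-length(s)] != "toxic")
    }
    g
  }
  for (try in 1:500) {
    tox <- sim_mk(tree, Qt, root_prior = "equal")
    gains <- count_gains(tox)
    if (min(table(factor(tox, c("nontoxic", "toxic")))) >= 0.15 * n &&
        gains >= 3L) break
    if (try == 500L)
      stop("could not simulate a balanced, repeatedly shifting toxicity ",
           "character", call. = FALSE)
  }
  flip <- stats::runif(n) < (1 - config$host_correlation) / 2
  veg_sparse <- (tox == "toxic") != flip  # sparse iff toxic, modulo flips
  vegetation <- ifelse(veg_sparse, "sparse", "dense")

  lat <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  distribution <- cut(lat, c(-Inf, -0.5, 0.5, Inf),
                      labels = c("temperate", "both", "tropical"))
  toxic_fams <- c("Aristolochiaceae", "Crassulaceae", "Papaveraceae",
                  "Zygophyllaceae")
  nontoxic_fams <- c("Apiaceae", "Rutaceae", "Lauraceae", "Annonaceae",
                     "Fabaceae")
  family <- ifelse(tox == "toxic",
                   sample(toxic_fams, n, replace = TRUE),
                   sample(nontoxic_fams, n, replace = TRUE))
  out <- data.frame(species = tree$tip.label, family = family,
                    toxicity = as.character(tox),
                    vegetation = vegetation,
                    distribution = as.character(distribution),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(toxicity_gains = gains,
                             toxicity_node_states = attr(tox, "node_states"),
                             flipped_tips = tree$tip.label[flip])
  out
}

#' Simulate defense phenotypes per lifestage
#'
#' Host-driven generating rule: tips on toxic (sparse) hosts are aposematic at
#' both instar stages with probability `1 - epsilon`; tips on nontoxic (dense)
#' hosts masquerade at early instars and are cryptic at late instars with
#' probability `1 - epsilon`. With probability `epsilon` a tip breaks the host
#' rule by switching apparency: an expected apparent state (aposematism or
#' masquerade) becomes crypsis, and expected crypsis becomes aposematism —
#' the direction real exceptions take (cryptic lineages on toxic sparse hosts,
#' aposematic lineages on dense nontoxic hosts). All pupae are cryptic. The
#' generating rule and the exception tips are recorded as ground truth.
#'
#' @param tree a `phylo` object.
#' @param host host table from [sim_host_traits()].
#' @param config a [synth_config()].
#' @param seed optional override seed.
#' @return List with named character vectors `early`, `late`, `pupa` over the
#'   tips and attribute `truth` (expected state per tip and exception lists).
#' @export
sim_defense_states <- function(tree, host, config = synth_config(),
                               seed = NULL) {
  old <- local_seed((seed %||% config$seed) + 2L)
  on.exit(restore_seed(old), add = TRUE)
  tree <- validate_tree(tree)
  if (!all(tree$tip.label %in% host$species))
    stop("host table does not cover the tree tips", call. = FALSE)
  host <- host[match(tree$tip.label, host$species), ]
  n <- nrow(host)
  draw <- function(expected) {
    dev <- stats::runif(n) < config$epsilon
    out <- expected
    out[dev] <- ifelse(expected[dev] == "crypsis", "aposematism", "crypsis")
    list(states = stats::setNames(out, tree$tip.label),
         exceptions = tree$tip.label[dev])
  }
  exp_early <- ifelse(host$toxicity == "toxic", "aposematism", "masquerade")
  exp_late <- ifelse(host$toxicity == "toxic", "aposematism", "crypsis")
  early <- draw(exp_early)
  late <- draw(exp_late)
  pupa <- stats::setNames(rep("crypsis", n), tree$tip.label)
  out <- list(early = early$states, late = late$states, pupa = pupa)
  attr(out, "truth") <- list(
    expected_early = stats::setNames(exp_early, tree$tip.label),
    expected_late = stats::setNames(exp_late, tree$tip.label),
    exceptions_early = early$exceptions,
    exceptions_late = late$exceptions)
  out
}

clamp255 <- function(x) pmin(255, pmax(0, round(x)))

#' Generate a colour scene for a strategy
#'
#' Builds a (foreground, background) composition pair whose palettes follow
#' the strategy: cryptic foregrounds match the background dominant colour to
#' within 10 per channel; masquerading foregrounds are whites/grays (channel
#' spread at most 20, mean at least 150) on a green-dominated background;
#' aposematic foregrounds have a dark base with red and yellow secondary
#' colours. Dominant proportions always exceed 0.25, and
#' [classify_strategy()] recovers the generating strategy at the default
#' thresholds.
#'
#' @param strategy `"masquerade"`, `"crypsis"` or `"aposematism"`.
#' @param config a [synth_config()] (unused fields reserved).
#' @param seed integer seed.
#' @return List with elements `foreground` and `background`, both
#'   [color_composition()] objects.
#' @export
gen_color_scene <- function(strategy = c("masquerade", "crypsis",
                                         "aposematism"),
                            config = synth_config(), seed = 1L) {
  strategy <- match.arg(strategy)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # green-dominated vegetation background
  bg_dom <- clamp255(c(70, 120, 50) + stats::runif(3, -15, 15))
  bg_sec <- clamp255(bg_dom + c(-25, 30, -10) + stats::runif(3, -8, 8))
  if (all(bg_sec == bg_dom)) bg_sec <- clamp255(bg_sec + c(5, 10, 5))
  background <- color_composition(
    r = c(bg_dom[1], bg_sec[1]), g = c(bg_dom[2], bg_sec[2]),
    b = c(bg_dom[3], bg_sec[3]), proportion = c(0.65, 0.35))

  fg <- switch(strategy,
    crypsis = {
      fdom <- clamp255(bg_dom + stats::runif(3, -10, 10))
      fsec <- clamp255(fdom + c(12, -12, 8))
      list(cols = rbind(fdom, fsec), props = c(0.7, 0.3))
    },
    masquerade = {
      base <- stats::runif(1, 170, 235)
      fdom <- clamp255(base + stats::runif(3, -5, 5))
      fsec <- clamp255(fdom - stats::runif(1, 25, 45))
      list(cols = rbind(fdom, fsec), props = c(0.6, 0.4))
    },
    aposematism = {
      dark <- clamp255(c(25, 25, 25) + stats::runif(3, -10, 10))
      red <- clamp255(c(210, 35, 30) + stats::runif(3, -15, 15))
      yellow <- clamp255(c(235, 200, 30) + stats::runif(3, -15, 15))
      list(cols = rbind(dark, red, yellow), props = c(0.45, 0.3, 0.25))
    })
  foreground <- color_composition(fg$cols[, 1], fg$cols[, 2], fg$cols[, 3],
                                  fg$props)
  list(foreground = foreground, background = background)
}

#' Render a composition as a pixel sample
#'
#' Draws `n_pixels` pixels from a composition's colours in proportion, with
#' optional Gaussian channel noise — a synthetic stand-in for a photographed
#' image region, used to exercise [extract_color_gamut()].
#'
#' @param comp a [color_composition()].
#' @param n_pixels number of pixels (default 1000).
#' @param noise_sd per-channel Gaussian noise SD (default 0 = exact colours).
#' @param seed integer seed.
#' @return An `n_pixels x 3` integer matrix.
#' @export
render_composition <- function(comp, n_pixels = 1000L, noise_sd = 0,
                               seed = 1L) {
  comp <- validate_composition(comp)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  idx <- sample.int(nrow(comp), n_pixels, replace = TRUE,
                    prob = comp$proportion)
  px <- as.matrix(comp[idx, c("r", "g", "b")])
  if (noise_sd > 0)
    px <- clamp255(px + matrix(stats::rnorm(3 * n_pixels, 0, noise_sd),
                               ncol = 3))
  storage.mode(px) <- "integer"
  dimnames(px) <- NULL
  px
}

#' Simulate a full synthetic dataset
#'
#' Generates the tree, host table, per-lifestage defense states and one colour
#' scene per species and lifestage, optionally writing them to disk as
#' `tree.nwk`, `hosts.csv`, `traits.csv`, `scenes.csv` and `truth.json`.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory.
#' @return List: `tree`, `hosts`, `defense` (list early/late/pupa), `scenes`
#'   (long composition data frame), `truth`.
#' @export
simulate_dataset <- function(config = synth_config(), dir = NULL) {
  tree <- gen_tree(config)
  hosts <- sim_host_traits(tree, config)
  defense <- sim_defense_states(tree, hosts, config)
  n <- ape::Ntip(tree)
  stages <- c("early", "late", "pupa")
  scene_rows <- list()
  for (st in stages) {
    for (i in seq_len(n)) {
      sp <- tree$tip.label[i]
      scene_seed <- as.integer((as.numeric(config$seed) * 1000 +
                                  match(st, stages) * 100 + i) %% 2147483647)
      sc <- gen_color_scene(defense[[st]][[sp]], config, seed = scene_seed)
      for (role in c("foreground", "background")) {
        cmp <- sc[[role]]
        scene_rows[[length(scene_rows) + 1L]] <- data.frame(
          species = sp, lifestage = st, role = role,
          r = cmp$r, g = cmp$g, b = cmp$b, proportion = cmp$proportion)
      }
    }
  }
  scenes <- do.call(rbind, scene_rows)
  truth <- list(
    seed = config$seed,
    toxicity_gains = attr(hosts, "truth")$toxicity_gains,
    exceptions_early = attr(defense, "truth")$exceptions_early,
    exceptions_late = attr(defense, "truth")$exceptions_late)
  out <- list(tree = tree, hosts = hosts, defense = defense, scenes = scenes,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tree(tree, file.path(dir, "tree.nwk"))
    utils::write.csv(hosts, file.path(dir, "hosts.csv"), row.names = FALSE)
    traits <- do.call(rbind, lapply(stages, function(st)
      data.frame(species = tree$tip.label, lifestage = st,
                 state = unname(defense[[st]][tree$tip.label]))))
    utils::write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
    utils::write.csv(scenes, file.path(dir, "scenes.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
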