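# Synthetic-data generator: determinism, calibration of the host-character
# concordance, host-driven phenotypes, and scene/classifier consistency.

test_that("tree generation is seeded, unit-height and conditioned on n", {
  cfg <- synth_config(n_tips = 2, seed = 5)
  cherry <- gen_tree(cfg)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_equal(max(ape::node.depth.edgelength(cherry)), 1, tolerance = 1e-12)

  cfg63 <- synth_config(seed = 42)
  t1 <- gen_tree(cfg63)
  t2 <- gen_tree(cfg63)
  expect_identical(write_tree(t1), write_tree(t2))
  expect_equal(ape::Ntip(t1), 63L)
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-12)

  t3 <- gen_tree(cfg63, seed = 43)
  expect_false(identical(write_tree(t1), write_tree(t3)))
})

test_that("host traits honour the concordance target and partition tips", {
  cfg <- synth_config(seed = 7)
  tr <- gen_tree(cfg)

  perfect <- sim_host_traits(tr, synth_config(host_correlation = 1, seed = 7))
  expect_identical(perfect$vegetation == "sparse",
                   perfect$toxicity == "toxic")

  set.seed(83)
  conc <- replicate(100, {
    h <- sim_host_traits(tr, cfg, seed = sample.int(1e6, 1))
    mean((h$vegetation == "sparse") == (h$toxicity == "toxic"))
  })
  # flip probability (1 - 0.9)/2 = 0.05 -> expected concordance 0.95
  expect_lt(abs(mean(conc) - 0.95), 0.02)

  h <- sim_host_traits(tr, cfg)
  expect_true(all(h$distribution %in% c("temperate", "tropical", "both")))
  expect_equal(nrow(h), 63L)
  expect_setequal(h$species, tr$tip.label)
  # both host types well represented
  expect_gte(min(table(h$toxicity)), ceiling(0.15 * 63))
  expect_true(all(h$family[h$toxicity == "toxic"] %in%
                    c("Aristolochiaceae", "Crassulaceae", "Papaveraceae",
                      "Zygophyllaceae")))
})

test_that("defense states follow the host rule with calibrated exceptions", {
  cfg0 <- synth_config(epsilon = 0, seed = 11)
  tr <- gen_tree(cfg0)
  h <- sim_host_traits(tr, cfg0)
  d0 <- sim_defense_states(tr, h, cfg0)
  toxic <- h$toxicity[match(names(d0$early), h$species)] == "toxic"
  expect_true(all(d0$early[toxic] == "aposematism"))
  expect_true(all(d0$early[!toxic] == "masquerade"))
  expect_true(all(d0$late[toxic] == "aposematism"))
  expect_true(all(d0$late[!toxic] == "crypsis"))
  expect_true(all(d0$pupa == "crypsis"))

  cfg <- synth_config(epsilon = 0.05, seed = 11)
  set.seed(89)
  nexc <- replicate(40, {
    d <- sim_defense_states(tr, h, cfg, seed = sample.int(1e6, 1))
    length(attr(d, "truth")$exceptions_late)
  })
  # Binomial(63, 0.05): mean 3.15; the replicate mean should sit within
  # 3 standard errors
  expect_lt(abs(mean(nexc) - 63 * 0.05), 3 * sqrt(63 * 0.05 * 0.95 / 40))
})

test_that("colour scenes match their construction rules and are recoverable", {
  cfg <- synth_config(seed = 1)
  for (i in 1:20) {
    sc <- gen_color_scene("crypsis", cfg, seed = i)
    d <- delta_rgb(dominant_color(sc$background), dominant_color(sc$foreground))
    expect_lte(sqrt(sum(as.numeric(d)^2)), sqrt(3) * 10 + 1e-9)

    sm <- gen_color_scene("masquerade", cfg, seed = i)
    fg <- sm$foreground
    spread <- apply(as.matrix(fg[, c("r", "g", "b")]), 1,
                    function(x) max(x) - min(x))
    expect_true(all(spread <= 20))
    expect_true(all(rowMeans(as.matrix(fg[, c("r", "g", "b")])) >= 100))
  }
  s1 <- gen_color_scene("aposematism", cfg, seed = 99)
  s2 <- gen_color_scene("aposematism", cfg, seed = 99)
  expect_identical(s1, s2)
})

test_that("the classifier recovers the generating strategy", {
  cfg <- synth_config(seed = 1)
  strategies <- rep(c("masquerade", "crypsis", "aposematism"), each = 20)
  got <- vapply(seq_along(strategies), function(i) {
    sc <- gen_color_scene(strategies[i], cfg, seed = 1000 + i)
    d <- delta_rgb(dominant_color(sc$background),
                   dominant_color(sc$foreground))
    classify_strategy(d, sc$foreground)$strategy
  }, character(1))
  expect_identical(got, strategies)
})

test_that("rendered pixels reproduce the composition proportions", {
  comp <- color_composition(c(200, 30), c(40, 160), c(40, 90), c(0.7, 0.3))
  px <- render_composition(comp, n_pixels = 4000, seed = 3)
  back <- extract_color_gamut(px, max_colors = 2)
  expect_equal(back$proportion[1], 0.7, tolerance = 0.03)
  expect_identical(render_composition(comp, n_pixels = 100, seed = 3),
                   render_composition(comp, n_pixels = 100, seed = 3))
})

test_that("whole datasets are byte-identical under a fixed seed", {
  d1 <- simulate_dataset(synth_config(seed = 4))
  d2 <- simulate_dataset(synth_config(seed = 4))
  expect_identical(write_tree(d1$tree), write_tree(d2$tree))
  expect_identical(d1$hosts, d2$hosts)
  expect_identical(d1$defense, d2$defense)
  expect_identical(d1$scenes, d2$scenes)

  dir <- withr::local_tempdir()
  simulate_dataset(synth_config(seed = 4), dir = dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "hosts.csv",
                                               "traits.csv", "scenes.csv",
                                               "truth.json")))))
  reread <- read_tree(file = file.path(dir, "tree.nwk"))
  expect_identical(write_tree(reread), write_tree(d1$tree))
})
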