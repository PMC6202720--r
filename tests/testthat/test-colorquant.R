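# Palette extraction, dominant colours, delta RGB and the apparency /
# background-matching statistics.

test_that("colour gamut extraction recovers exact palettes of simple images", {
  uni <- matrix(rep(c(0, 0, 0), each = 100), ncol = 3)
  comp <- extract_color_gamut(uni, max_colors = 5)
  expect_s3_class(comp, "color_composition")
  expect_equal(nrow(comp), 1L)
  expect_equal(unlist(comp[1, c("r", "g", "b")], use.names = FALSE), c(0, 0, 0))
  expect_equal(comp$proportion, 1)

  px <- rbind(matrix(rep(c(255, 0, 0), each = 60), ncol = 3),
              matrix(rep(c(0, 0, 255), each = 40), ncol = 3))
  comp <- extract_color_gamut(px, max_colors = 2)
  expect_equal(comp$proportion, c(0.6, 0.4))
  expect_equal(comp$r, c(255, 0))
  expect_equal(comp$b, c(0, 255))
  expect_equal(comp$rank, c(1L, 2L))

  expect_error(extract_color_gamut(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("gamut extraction recovers Gaussian cluster weights and is invariant to pixel order", {
  set.seed(101)
  centers <- rbind(c(200, 40, 40), c(40, 200, 40), c(40, 40, 200))
  weights <- c(0.5, 0.3, 0.2)
  n <- 2000
  comp_idx <- sample.int(3, n, replace = TRUE, prob = weights)
  px <- pmin(pmax(round(centers[comp_idx, ] +
                          matrix(rnorm(3 * n, 0, 12), ncol = 3)), 0), 255)
  comp <- extract_color_gamut(px, max_colors = 3, seed = 7)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)

  # oracle: exhaustive nearest-centroid assignment to the true centers
  d2 <- sapply(1:3, function(j)
    rowSums((px - matrix(centers[j, ], n, 3, byrow = TRUE))^2))
  oracle_prop <- tabulate(max.col(-d2), 3) / n
  # match extracted entries to true centers by nearest distance
  got <- sapply(1:3, function(j) {
    dd <- rowSums((as.matrix(comp[, c("r", "g", "b")]) -
                     matrix(centers[j, ], nrow(comp), 3, byrow = TRUE))^2)
    comp$proportion[which.min(dd)]
  })
  expect_true(all(abs(got - oracle_prop) <= 0.05))
  expect_true(all(abs(got - weights) <= 0.05))

  # permutation invariance
  perm <- sample.int(n)
  comp2 <- extract_color_gamut(px[perm, ], max_colors = 3, seed = 7)
  expect_identical(comp, comp2)
})

test_that("dominant colour applies the >threshold rule with lexicographic tie-break", {
  comp <- color_composition(c(255, 128, 0), c(255, 128, 200), c(255, 128, 0),
                            c(0.6, 0.3, 0.1))
  d <- dominant_color(comp)
  expect_equal(unname(d$color), c(255, 255, 255))
  expect_equal(d$proportion, 0.6)

  five <- color_composition(seq(10, 50, 10), seq(10, 50, 10), seq(10, 50, 10),
                            rep(0.2, 5))
  expect_error(dominant_color(five), "no dominant colour")

  tie <- color_composition(c(10, 200, 30), c(10, 0, 200), c(10, 0, 100),
                           c(0.4, 0.4, 0.2))
  expect_equal(unname(dominant_color(tie)$color), c(10, 10, 10))
})

test_that("delta RGB is an absolute, symmetric, bounded per-channel contrast", {
  expect_equal(unname(unclass(delta_rgb(c(255, 255, 255), c(255, 255, 255)))),
               c(0, 0, 0))
  expect_equal(unname(unclass(delta_rgb(c(120, 200, 80), c(30, 40, 50)))),
               c(90, 160, 30))
  expect_equal(unname(unclass(delta_rgb(c(0, 0, 0), c(255, 255, 255)))),
               c(255, 255, 255))
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:255, 3); b <- sample(0:255, 3)
    expect_identical(unclass(delta_rgb(a, b)), unclass(delta_rgb(b, a)))
    expect_true(all(unclass(delta_rgb(a, b)) <= 255))
    expect_equal(unname(unclass(delta_rgb(a, a))), c(0, 0, 0))
  }
})

test_that("apparency test matches the exact rank-sum oracle and flags degeneracy", {
  # deltas whose only variation is on one channel, so PC1 is that channel
  vals <- c(1, 2, 3, 4, 5, 6)
  deltas <- cbind(dr = vals * 10, dg = 0, db = 0)
  rownames(deltas) <- paste0("s", 1:6)
  labels <- setNames(rep(c("apparent", "nonapparent"), each = 3),
                     rownames(deltas))
  res <- apparency_test(deltas, labels)
  pc1 <- res$pc_scores[, 1]
  W_oracle <- count_pairs_W(pc1[1:3], pc1[4:6])
  expect_equal(res$w_statistic, W_oracle)
  expect_equal(res$p_value, exact_mw_p(pc1[1:3], pc1[4:6]))
  expect_equal(res$p_value, 0.1)
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(res$variance_explained) <= 1e-12))

  same <- matrix(5, 6, 3, dimnames = list(rownames(deltas),
                                          c("dr", "dg", "db")))
  expect_error(apparency_test(same, labels), "degenerate")
  expect_error(apparency_test(deltas, setNames(c("apparent",
                                                 rep("nonapparent", 5)),
                                               rownames(deltas))),
               "insufficient")
})

test_that("PC scores are stable (up to sign) under species reordering", {
  set.seed(9)
  D <- matrix(sample(0:255, 30, TRUE), 10, 3,
              dimnames = list(paste0("s", 1:10), c("dr", "dg", "db")))
  labs <- setNames(rep(c("apparent", "nonapparent"), 5), rownames(D))
  r1 <- apparency_test(D, labs)
  perm <- sample(rownames(D))
  r2 <- apparency_test(D[perm, ], labs[perm])
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  agree <- abs(sum(sign(r1$pc_scores[perm, 1] * r2$pc_scores[, 1])))
  expect_equal(agree, 10)  # all same sign or all flipped
})

test_that("pupa background-match test behaves at the identical and extreme poles", {
  set.seed(3)
  cols <- matrix(sample(0:255, 30, TRUE), 10, 3)
  res <- pupa_match_test(cols, cols)
  expect_equal(res$p_value, rep(1, 3))

  black <- matrix(0, 10, 3)
  white <- matrix(255, 10, 3)
  res2 <- pupa_match_test(black, white)
  expect_true(all(res2$p_value < 0.01))

  expect_error(pupa_match_test(black, white[1:5, ]), "length")
})

test_that("same-distribution pupa samples are rarely declared mismatched", {
  set.seed(77)
  ok <- replicate(100, {
    a <- matrix(sample(0:255, 90, TRUE), 30, 3)
    b <- matrix(sample(0:255, 90, TRUE), 30, 3)
    pupa_match_test(a, b)$p_value > 0.05
  })
  # per-channel calibration: a 5%-level test flags at most ~10% of null draws
  expect_true(all(rowMeans(ok) >= 0.9))
})

test_that("strategy classification follows the contrast and palette rules", {
  gray_comp <- color_composition(c(250, 128), c(250, 128), c(250, 128),
                                 c(0.6, 0.4))
  warn_comp <- color_composition(c(10, 210, 235), c(10, 30, 200),
                                 c(10, 25, 30), c(0.5, 0.3, 0.2))
  low <- delta_rgb(c(10, 10, 10), c(5, 7, 8))
  expect_equal(classify_strategy(low, warn_comp)$strategy, "crypsis")
  expect_equal(classify_strategy(low, warn_comp)$apparency, "nonapparent")

  high <- delta_rgb(c(200, 180, 190), c(0, 0, 0))
  expect_equal(classify_strategy(high, gray_comp)$strategy, "masquerade")
  expect_equal(classify_strategy(high, gray_comp)$apparency, "apparent")

  mid <- delta_rgb(c(150, 90, 120), c(0, 0, 0))
  expect_equal(classify_strategy(mid, warn_comp)$strategy, "aposematism")
})

test_that("PNG images are read with fully transparent pixels masked out", {
  # 10x10 image: left half solid red, right half fully transparent white
  img <- array(0, dim = c(10, 10, 4))
  img[, 1:5, 1] <- 1                 # red channel
  img[, 1:5, 4] <- 1                 # opaque
  img[, 6:10, 1:3] <- 1              # white, alpha 0 (mask)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  comp <- read_image_composition(path, max_colors = 4)
  expect_equal(nrow(comp), 1L)
  expect_equal(unlist(comp[1, c("r", "g", "b")], use.names = FALSE),
               c(255, 0, 0))
  expect_equal(comp$proportion, 1)
})

test_that("compositions enforce their invariants", {
  expect_error(color_composition(300, 0, 0, 1), "\\[0, 255\\]")
  expect_error(color_composition(c(1, 2), c(1, 2), c(1, 2), c(0.5, 0.4)),
               "sum to 1")
  expect_error(color_composition(c(1, 1), c(2, 2), c(3, 3), c(0.5, 0.5)),
               "duplicate")
})
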