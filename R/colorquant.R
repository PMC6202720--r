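# Colour quantification: palette extraction, dominant colours, delta RGB
# contrast, strategy classification and the apparency / background-match tests.

#' Build a colour composition
#'
#' A colour composition is the ranked palette of an image region: one row per
#' colour with integer RGB channels in \[0, 255\] and the relative proportion
#' of the region covered by that colour. Proportions must sum to one; rank 1
#' is the largest proportion.
#'
#' @param r,g,b integer channel vectors in \[0, 255\].
#' @param proportion numeric vector of relative proportions in (0, 1], summing
#'   to 1 (tolerance 1e-6).
#' @return A `data.frame` of class `"color_composition"` with columns
#'   `r`, `g`, `b`, `proportion`, `rank`, ordered by decreasing proportion
#'   (ties broken by lexicographically smallest RGB).
#' @export
color_composition <- function(r, g, b, proportion) {
  comp <- data.frame(r = as.integer(round(r)), g = as.integer(round(g)),
                     b = as.integer(round(b)), proportion = as.numeric(proportion))
  validate_composition(comp)
}

validate_composition <- function(comp) {
  stopifnot(is.data.frame(comp), nrow(comp) >= 1L,
            all(c("r", "g", "b", "proportion") %in% names(comp)))
  ch <- as.matrix(comp[, c("r", "g", "b")])
  if (any(ch < 0 | ch > 255) || any(ch != round(ch)))
    stop("colour channels must be integers in [0, 255]", call. = FALSE)
  if (any(comp$proportion <= 0) || abs(sum(comp$proportion) - 1) > 1e-6)
    stop("proportions must be positive and sum to 1", call. = FALSE)
  key <- paste(comp$r, comp$g, comp$b)
  if (anyDuplicated(key))
    stop("duplicate colours in composition", call. = FALSE)
  o <- order(-comp$proportion, comp$r, comp$g, comp$b)
  comp <- comp[o, c("r", "g", "b", "proportion"), drop = FALSE]
  comp$rank <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  class(comp) <- c("color_composition", "data.frame")
  comp
}

# Coerce pixel input (n x 3 matrix, h x w x 3 or h x w x 4 array in 0..255 or
# 0..1) to an n x 3 integer matrix; fully transparent pixels are dropped.
as_pixel_matrix <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    d <- dim(pixels)
    if (!d[3] %in% c(3L, 4L))
      stop("pixel array must have 3 (RGB) or 4 (RGBA) channels", call. = FALSE)
    m <- matrix(pixels, ncol = d[3])
    if (d[3] == 4L) {
      m <- m[m[, 4] > 0, 1:3, drop = FALSE]  # alpha == 0 excluded (mask)
    }
  } else {
    m <- as.matrix(pixels)
    if (ncol(m) != 3L) stop("pixel matrix must have 3 columns", call. = FALSE)
  }
  if (nrow(m) == 0L) stop("empty pixel grid", call. = FALSE)
  if (max(m) <= 1 && min(m) >= 0) m <- m * 255
  storage.mode(m) <- "double"
  round(m)
}

#' Extract the colour gamut of an image region
#'
#' Quantizes the pixels of an image region into at most `max_colors` colours by
#' seeded k-means in RGB space and returns the resulting palette with relative
#' proportions. Pixels are canonically sorted before clustering, so the result
#' is invariant to pixel-order permutation; with `seed` fixed the output is
#' fully deterministic. Clusters holding less than `min_proportion` of the
#' pixels are merged into the nearest retained centroid.
#'
#' @param pixels an `n x 3` matrix of RGB values, or an `h x w x 3` (RGB) /
#'   `h x w x 4` (RGBA) array; values either in \[0, 255\] or \[0, 1\]. Fully
#'   transparent pixels (alpha = 0) are treated as background mask and dropped.
#' @param max_colors maximum number of palette entries (default 8).
#' @param seed integer seed for the k-means initialisation.
#' @param min_proportion clusters below this fraction are merged into their
#'   nearest centroid (default 0.01).
#' @return A [color_composition()].
#' @export
extract_color_gamut <- function(pixels, max_colors = 8L, seed = 1L,
                                min_proportion = 0.01) {
  px <- as_pixel_matrix(pixels)
  if (max_colors < 1L) stop("max_colors must be >= 1", call. = FALSE)
  px <- px[order(px[, 1], px[, 2], px[, 3]), , drop = FALSE]
  n <- nrow(px)
  key <- paste(px[, 1], px[, 2], px[, 3])
  uk <- !duplicated(key)
  uniq <- px[uk, , drop = FALSE]

  if (nrow(uniq) <= max_colors) {
    cnt <- as.vector(table(factor(key, levels = key[uk])))
    centers <- uniq
    props <- cnt / n
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    km <- suppressWarnings(
      stats::kmeans(px, centers = max_colors, iter.max = 100L, nstart = 5L)
    )
    centers <- km$centers
    props <- as.vector(km$size) / n
    keep <- props >= min_proportion
    if (!all(keep) && any(keep)) {
      big <- which(keep)
      for (i in which(!keep)) {
        d2 <- rowSums((centers[big, , drop = FALSE] -
                         matrix(centers[i, ], length(big), 3, byrow = TRUE))^2)
        j <- big[which.min(d2)]
        # weighted centroid update, then fold the proportion in
        w <- props[j] + props[i]
        centers[j, ] <- (centers[j, ] * props[j] + centers[i, ] * props[i]) / w
        props[j] <- w
      }
      centers <- centers[big, , drop = FALSE]
      props <- props[big]
    }
  }

  centers <- round(centers)
  # merge palette entries that collide after rounding
  key2 <- paste(centers[, 1], centers[, 2], centers[, 3])
  if (anyDuplicated(key2)) {
    props <- as.vector(tapply(props, factor(key2, levels = unique(key2)), sum))
    centers <- centers[!duplicated(key2), , drop = FALSE]
  }
  color_composition(centers[, 1], centers[, 2], centers[, 3], props / sum(props))
}

#' Read an image file as a colour composition
#'
#' Reads an 8-bit RGB(A) PNG and quantizes it with [extract_color_gamut()].
#' Fully transparent pixels are treated as the cut-out mask and excluded,
#' matching background-separated lifestage images.
#'
#' @param path path to a PNG file.
#' @inheritParams extract_color_gamut
#' @export
read_image_composition <- function(path, max_colors = 8L, seed = 1L,
                                   min_proportion = 0.01) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to read PNG images", call. = FALSE)
  extract_color_gamut(png::readPNG(path), max_colors = max_colors,
                      seed = seed, min_proportion = min_proportion)
}

#' Dominant colour of a composition
#'
#' The primary colour of an image region: the highest-proportion palette entry,
#' provided it exceeds the dominance threshold (default 25% of the region).
#' Ties are broken by the lexicographically smallest (r, g, b).
#'
#' @param comp a [color_composition()].
#' @param threshold dominance threshold as a fraction; the top entry must have
#'   `proportion > threshold` (default 0.25).
#' @return A list of class `"dominant_color"` with elements `color` (named
#'   integer vector r, g, b) and `proportion`.
#' @export
dominant_color <- function(comp, threshold = 0.25) {
  comp <- validate_composition(comp)
  top <- comp[1L, ]  # already sorted: max proportion, lexicographic tie-break
  if (!(top$proportion > threshold))
    stop("no dominant colour: largest proportion ", signif(top$proportion, 3),
         " does not exceed threshold ", threshold, call. = FALSE)
  structure(list(color = c(r = top$r, g = top$g, b = top$b),
                 proportion = top$proportion),
            class = "dominant_color")
}

as_rgb_vec <- function(x) {
  if (inherits(x, "dominant_color")) x <- x$color
  x <- as.numeric(x)[1:3]
  if (any(is.na(x)) || any(x < 0 | x > 255))
    stop("not an RGB colour in [0, 255]", call. = FALSE)
  x
}

#' Delta RGB colour contrast
#'
#' The per-channel absolute difference between the dominant colour of a visual
#' background and that of a lifestage. Delta RGB is not a colour but a
#' conspicuousness estimate: large values mean the animal stands out from its
#' background, near-zero values mean background matching.
#'
#' @param background,lifestage dominant colours (from [dominant_color()]) or
#'   RGB triplets.
#' @return Named integer vector `c(dr, dg, db)` of class `"delta_rgb"`.
#' @export
delta_rgb <- function(background, lifestage) {
  d <- abs(as_rgb_vec(background) - as_rgb_vec(lifestage))
  structure(c(dr = d[1], dg = d[2], db = d[3]), class = "delta_rgb")
}

#' Apparency test on delta RGB scores
#'
#' Performs a principal component analysis on the three delta RGB channels
#' (centred, not rescaled: the channels share the 0-255 unit) and compares the
#' PC1 scores of apparent (masquerading or aposematic) versus nonapparent
#' (cryptic) species with a two-sided Mann-Whitney test. The reported W is the
#' rank-sum statistic of the apparent group minus its minimum (the U statistic
#' of group 1, R's `wilcox.test` convention). Exact p-values are used for
#' small untied samples, otherwise the tie-corrected normal approximation.
#'
#' @param deltas matrix or data.frame with one row per species and columns
#'   `dr`, `dg`, `db`; rownames (or a `species` column) identify species.
#' @param labels character/factor per species, `"apparent"` or `"nonapparent"`,
#'   named by species or aligned with `deltas`.
#' @return List of class `"apparency_test"`: `pc_scores` (matrix of PC1-PC3),
#'   `variance_explained`, `w_statistic`, `p_value`, `n_apparent`,
#'   `n_nonapparent`.
#' @export
apparency_test <- function(deltas, labels) {
  if (is.data.frame(deltas) && "species" %in% names(deltas)) {
    rownames(deltas) <- deltas$species
    deltas <- deltas[, c("dr", "dg", "db")]
  }
  D <- as.matrix(deltas)
  if (ncol(D) != 3L) stop("deltas must have three channel columns", call. = FALSE)
  if (!is.null(names(labels)) && !is.null(rownames(D))) {
    miss <- setdiff(rownames(D), names(labels))
    if (length(miss))
      stop("labels missing for species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    labels <- labels[rownames(D)]
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("apparent", "nonapparent")))
    stop("labels must be 'apparent' or 'nonapparent'", call. = FALSE)
  if (sum(lab == "apparent") < 2L || sum(lab == "nonapparent") < 2L)
    stop("insufficient data: need >= 2 species per apparency group", call. = FALSE)
  if (all(apply(D, 2, stats::var) < 1e-12))
    stop("degenerate input: delta RGB has zero total variance", call. = FALSE)

  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
  # orient each component so its loadings sum positive: all three channels
  # measure contrast positively, so PC1 then increases with conspicuousness
  flip <- colSums(pc$rotation) < 0
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  pc1 <- pc$x[, 1]
  wt <- suppressWarnings(
    stats::wilcox.test(pc1[lab == "apparent"], pc1[lab == "nonapparent"],
                       alternative = "two.sided")
  )
  structure(list(pc_scores = pc$x, variance_explained = ve,
                 w_statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_apparent = sum(lab == "apparent"),
                 n_nonapparent = sum(lab == "nonapparent")),
            class = "apparency_test")
}

#' Pupa background-matching test
#'
#' Compares pupal and background colours channel by channel (R, G, B) with a
#' two-group Kruskal-Wallis test. Pupae that match their backgrounds give
#' non-significant differences on every channel.
#'
#' @param pupa_colors,background_colors matrices/data.frames with columns
#'   `r`, `g`, `b`, one row per species, equal lengths (paired by species).
#' @return Data frame with one row per channel: `channel`, `statistic`, `df`,
#'   `p_value`.
#' @export
pupa_match_test <- function(pupa_colors, background_colors) {
  P <- as.matrix(pupa_colors)[, 1:3, drop = FALSE]
  B <- as.matrix(background_colors)[, 1:3, drop = FALSE]
  if (nrow(P) != nrow(B))
    stop("pupa and background colour tables differ in length", call. = FALSE)
  if (nrow(P) < 1L) stop("empty colour tables", call. = FALSE)
  g <- factor(rep(c("pupa", "background"), each = nrow(P)))
  res <- lapply(1:3, function(ch) {
    x <- c(P[, ch], B[, ch])
    if (stats::var(x) < 1e-12) {
      # all values tied across both groups: no detectable difference
      return(data.frame(channel = c("r", "g", "b")[ch], statistic = 0,
                        df = 1L, p_value = 1))
    }
    kt <- stats::kruskal.test(x, g)
    data.frame(channel = c("r", "g", "b")[ch],
               statistic = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value)
  })
  do.call(rbind, res)
}

#' Is a colour a shade of white or gray?
#'
#' @param color RGB triplet.
#' @param gray_tol maximum pairwise channel spread (default 30).
#' @param gray_min_mean minimum mean channel intensity (default 100).
#' @keywords internal
is_gray_white <- function(color, gray_tol = 30, gray_min_mean = 100) {
  x <- as_rgb_vec(color)
  (max(x) - min(x)) <= gray_tol && mean(x) >= gray_min_mean
}

#' Classify a colour-defense strategy
#'
#' Decision rule validated against natural-history classification: a lifestage
#' whose delta RGB contrast with its background falls below the apparency
#' threshold is cryptic (background matching). Apparent lifestages showing only
#' shades of white or gray (or colours close to a supplied reference palette,
#' e.g. a bird-dropping palette) masquerade; apparent lifestages with other
#' palettes — typically dark bases with red/yellow warning colours — are
#' aposematic.
#'
#' @param delta a [delta_rgb()] contrast.
#' @param lifestage_composition the lifestage [color_composition()].
#' @param apparency_threshold Euclidean norm of delta RGB at or above which a
#'   lifestage counts as apparent (default 60; channels in 0-255 units).
#' @param gray_tol,gray_min_mean gray/white rule: a colour is gray/white when
#'   its channel spread is at most `gray_tol` and its mean channel at least
#'   `gray_min_mean`.
#' @param reference_palette optional matrix of RGB rows (e.g. a bird-dropping
#'   palette); a colour within `palette_dist` (Euclidean) of any row also
#'   counts towards masquerade.
#' @param palette_dist distance for `reference_palette` matching (default 60).
#' @return List of class `"strategy_label"` with `strategy` (one of
#'   `"masquerade"`, `"crypsis"`, `"aposematism"`) and `apparency`
#'   (`"apparent"`/`"nonapparent"`).
#' @export
classify_strategy <- function(delta, lifestage_composition,
                              apparency_threshold = 60,
                              gray_tol = 30, gray_min_mean = 100,
                              reference_palette = NULL, palette_dist = 60) {
  d <- as.numeric(delta)[1:3]
  comp <- validate_composition(lifestage_composition)
  norm <- sqrt(sum(d^2))
  if (norm < apparency_threshold) {
    return(structure(list(strategy = "crypsis", apparency = "nonapparent"),
                     class = "strategy_label"))
  }
  masq_color <- function(col) {
    if (is_gray_white(col, gray_tol, gray_min_mean)) return(TRUE)
    if (!is.null(reference_palette)) {
      pal <- as.matrix(reference_palette)
      dd <- sqrt(rowSums((pal - matrix(col, nrow(pal), 3, byrow = TRUE))^2))
      return(any(dd <= palette_dist))
    }
    FALSE
  }
  all_masq <- all(vapply(seq_len(nrow(comp)), function(i)
    masq_color(c(comp$r[i], comp$g[i], comp$b[i])), logical(1)))
  structure(list(strategy = if (all_masq) "masquerade" else "aposematism",
                 apparency = "apparent"),
            class = "strategy_label")
}

#' Score contrast and classify strategies for a composition table
#'
#' Takes a long-format composition table (columns `species`, `lifestage`,
#' `role` = `"foreground"`/`"background"`, `r`, `g`, `b`, `proportion`) and,
#' per species and lifestage, computes dominant colours, delta RGB, and the
#' classified strategy.
#'
#' @param compositions long composition data.frame.
#' @param dominance_threshold passed to [dominant_color()].
#' @param ... further arguments passed to [classify_strategy()].
#' @return Data frame: `species`, `lifestage`, foreground/background dominant
#'   channels, `dr`, `dg`, `db`, `strategy`, `apparency`.
#' @export
score_contrast <- function(compositions, dominance_threshold = 0.25, ...) {
  need <- c("species", "lifestage", "role", "r", "g", "b", "proportion")
  if (!all(need %in% names(compositions)))
    stop("composition table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- unique(compositions[, c("species", "lifestage")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[i]; ls <- keys$lifestage[i]
    sub <- compositions[compositions$species == sp &
                          compositions$lifestage == ls, ]
    fg <- sub[sub$role == "foreground", ]
    bg <- sub[sub$role == "background", ]
    if (!nrow(fg) || !nrow(bg))
      stop("species ", sp, " lifestage ", ls,
           " lacks a foreground or background composition", call. = FALSE)
    fgc <- color_composition(fg$r, fg$g, fg$b, fg$proportion)
    bgc <- color_composition(bg$r, bg$g, bg$b, bg$proportion)
    fdom <- dominant_color(fgc, dominance_threshold)
    bdom <- dominant_color(bgc, dominance_threshold)
    d <- delta_rgb(bdom, fdom)
    cl <- classify_strategy(d, fgc, ...)
    data.frame(species = sp, lifestage = ls,
               fg_r = fdom$color[["r"]], fg_g = fdom$color[["g"]],
               fg_b = fdom$color[["b"]],
               bg_r = bdom$color[["r"]], bg_g = bdom$color[["g"]],
               bg_b = bdom$color[["b"]],
               dr = unname(d[1]), dg = unname(d[2]), db = unname(d[3]),
               strategy = cl$strategy, apparency = cl$apparency)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.apparency_test <- function(x, ...) {
  cat("Apparency test (PCA on delta RGB + Mann-Whitney on PC1)\n")
  cat(sprintf("  groups: %d apparent vs %d nonapparent\n",
              x$n_apparent, x$n_nonapparent))
  cat(sprintf("  PC variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  cat(sprintf("  W = %g, p = %.4g\n", x$w_statistic, x$p_value))
  invisible(x)
}

#' @export
print.strategy_label <- function(x, ...) {
  cat(sprintf("strategy: %s (%s)\n", x$strategy, x$apparency))
  invisible(x)
}
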