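# End-to-end orchestration: colour scoring -> strategy classification ->
# apparency binarization -> Mk fitting + stochastic mapping per lifestage ->
# phylogenetic logistic regression; machine-readable report.

#' Build a run configuration
#'
#' Collects input locations (or in-memory objects) and analysis thresholds.
#' Either supply `data` (a list as returned by [simulate_dataset()]) or the
#' paths `tree_file`, `hosts_file`, `scenes_file`.
#'
#' @param data optional in-memory dataset (`tree`, `hosts`, `scenes`, and
#'   optionally `defense`/`truth`).
#' @param tree_file,hosts_file,scenes_file input paths (Newick; CSV; long
#'   composition CSV) used when `data` is `NULL`.
#' @param dominance_threshold dominant-colour rule (default 0.25).
#' @param apparency_threshold delta RGB norm at which a lifestage is apparent
#'   (default 60).
#' @param gray_tol,gray_min_mean gray/white masquerade rule (defaults 30, 100).
#' @param nsim stochastic maps per lifestage (default 2000).
#' @param seed integer seed for the mapping step.
#' @param out_dir optional output directory for the report and tables.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(data = NULL, tree_file = NULL, hosts_file = NULL,
                       scenes_file = NULL, dominance_threshold = 0.25,
                       apparency_threshold = 60, gray_tol = 30,
                       gray_min_mean = 100, nsim = 2000L, seed = 1L,
                       out_dir = NULL) {
  stopifnot(dominance_threshold > 0, dominance_threshold < 1,
            apparency_threshold >= 0, gray_tol >= 0, nsim >= 1L)
  if (is.null(data) &&
      (is.null(tree_file) || is.null(hosts_file) || is.null(scenes_file)))
    stop("supply `data` or all of tree_file/hosts_file/scenes_file",
         call. = FALSE)
  structure(list(data = data, tree_file = tree_file, hosts_file = hosts_file,
                 scenes_file = scenes_file,
                 dominance_threshold = dominance_threshold,
                 apparency_threshold = apparency_threshold,
                 gray_tol = gray_tol, gray_min_mean = gray_min_mean,
                 nsim = as.integer(nsim), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$data)) {
    d <- config$data
    list(tree = validate_tree(d$tree), hosts = d$hosts, scenes = d$scenes)
  } else {
    list(tree = read_tree(file = config$tree_file),
         hosts = utils::read.csv(config$hosts_file, stringsAsFactors = FALSE),
         scenes = utils::read.csv(config$scenes_file,
                                  stringsAsFactors = FALSE))
  }
}

#' Validate pipeline inputs
#'
#' Checks that the tree parses and binds to the host table, that every
#' species/lifestage has foreground and background compositions whose
#' proportions sum to one, and that thresholds are in range. Returns a
#' validation report rather than failing on first error.
#'
#' @param config a [run_config()].
#' @return List of class `"validation_report"`: `ok` flag plus a character
#'   vector of named failures (empty when clean).
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  inp <- tryCatch(load_run_inputs(config), error = function(e) {
    problems <<- c(problems, paste("input loading:", conditionMessage(e)))
    NULL
  })
  if (!is.null(inp)) {
    tips <- inp$tree$tip.label
    need <- c("species", "toxicity", "vegetation", "distribution")
    miss_cols <- setdiff(need, names(inp$hosts))
    if (length(miss_cols))
      problems <- c(problems, paste("hosts table missing columns:",
                                    paste(miss_cols, collapse = ", ")))
    else {
      uncovered <- setdiff(tips, inp$hosts$species)
      if (length(uncovered))
        problems <- c(problems, paste("species missing from hosts table:",
                                      paste(uncovered, collapse = ", ")))
    }
    sc <- inp$scenes
    needs <- c("species", "lifestage", "role", "r", "g", "b", "proportion")
    if (!all(needs %in% names(sc))) {
      problems <- c(problems, paste("scenes table missing columns:",
                                    paste(setdiff(needs, names(sc)),
                                          collapse = ", ")))
    } else {
      key <- interaction(sc$species, sc$lifestage, sc$role, drop = TRUE)
      sums <- tapply(sc$proportion, key, sum)
      bad <- names(sums)[abs(sums - 1) > 1e-6]
      if (length(bad))
        problems <- c(problems,
                      paste("composition proportions do not sum to 1 for:",
                            paste(utils::head(bad, 10), collapse = ", ")))
      for (st in c("early", "late", "pupa")) {
        sub <- sc[sc$lifestage == st, ]
        for (role in c("foreground", "background")) {
          have <- unique(sub$species[sub$role == role])
          lack <- setdiff(tips, have)
          if (length(lack))
            problems <- c(problems,
                          sprintf("missing %s %s compositions for: %s", st,
                                  role, paste(utils::head(lack, 10),
                                              collapse = ", ")))
        }
      }
    }
  }
  structure(list(ok = length(problems) == 0L, problems = problems),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("inputs valid\n")
  else cat("validation failures:\n", paste("-", x$problems, collapse = "\n"),
           "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes colour scoring, strategy classification, the apparency and pupal
#' background-match statistics, Mk fitting and stochastic character mapping
#' per lifestage, origin counting, and the phylogenetic logistic regressions
#' (apparency ~ vegetation + distribution; toxicity/vegetation correlation).
#' The 3-level distribution label is encoded as tropical-vs-not with "both"
#' counted as tropical. Raw (uncorrected) p-values are reported throughout.
#'
#' @param config a [run_config()].
#' @return List of class `"analysis_report"` with sections `color` (per
#'   species/lifestage contrast table), `apparency_tests`, `pupa_match`,
#'   `mk` (per lifestage fit, ancestral summaries, origin counts),
#'   `phyloglm`, `predictor_correlation` and `provenance`. When
#'   `config$out_dir` is set, writes `report.json`, `contrast.csv` and
#'   per-lifestage `segments_<stage>.csv`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_run_inputs(config)
  tree <- inp$tree
  hosts <- inp$hosts[match(tree$tip.label, inp$hosts$species), ]
  stages <- intersect(c("early", "late", "pupa"), unique(inp$scenes$lifestage))

  contrast <- score_contrast(inp$scenes,
                             dominance_threshold = config$dominance_threshold,
                             apparency_threshold = config$apparency_threshold,
                             gray_tol = config$gray_tol,
                             gray_min_mean = config$gray_min_mean)

  apparency_tests <- list()
  for (st in intersect(c("early", "late"), stages)) {
    sub <- contrast[contrast$lifestage == st, ]
    deltas <- sub[, c("dr", "dg", "db")]
    rownames(deltas) <- sub$species
    labs <- stats::setNames(sub$apparency, sub$species)
    apparency_tests[[st]] <- tryCatch(apparency_test(deltas, labs),
                                      error = function(e)
                                        list(error = conditionMessage(e)))
  }

  pupa_match <- NULL
  if ("pupa" %in% stages) {
    sub <- contrast[contrast$lifestage == "pupa", ]
    pupa_match <- pupa_match_test(sub[, c("fg_r", "fg_g", "fg_b")],
                                  sub[, c("bg_r", "bg_g", "bg_b")])
  }

  all_states <- c("aposematism", "crypsis", "masquerade")
  mk <- list()
  for (st in stages) {
    sub <- contrast[contrast$lifestage == st, ]
    states <- stats::setNames(sub$strategy, sub$species)
    fit <- fit_mk(tree, states, model = "ER", state_names = all_states)
    maps <- sample_maps(tree, states, fit$Q, nsim = config$nsim,
                        seed = config$seed + match(st, stages))
    mk[[st]] <- list(
      fit = fit,
      marginal = marginal_ancestral(tree, states, fit$Q),
      node_summary = node_state_summary(maps),
      origins = lapply(stats::setNames(all_states, all_states),
                       function(s) count_origins(maps, s)),
      maps = maps)
  }

  late_stage <- if ("late" %in% stages) "late" else stages[1]
  sub <- contrast[contrast$lifestage == late_stage, ]
  y <- stats::setNames(as.integer(sub$apparency == "apparent"), sub$species)
  X <- data.frame(
    vegetation = as.integer(hosts$vegetation == "sparse"),
    distribution = as.integer(hosts$distribution %in% c("tropical", "both")),
    row.names = hosts$species)
  glm_fit <- tryCatch(fit_phyloglm(tree, y, X),
                      error = function(e) list(error = conditionMessage(e)))
  pc <- tryCatch(
    predictor_correlation(
      tree,
      stats::setNames(as.integer(hosts$toxicity == "toxic"), hosts$species),
      stats::setNames(as.integer(hosts$vegetation == "sparse"),
                      hosts$species)),
    error = function(e) list(error = conditionMessage(e)))

  report <- structure(list(
    color = contrast, apparency_tests = apparency_tests,
    pupa_match = pupa_match, mk = mk, phyloglm = glm_fit,
    predictor_correlation = pc,
    provenance = list(seed = config$seed, nsim = config$nsim,
                      thresholds = config[c("dominance_threshold",
                                            "apparency_threshold", "gray_tol",
                                            "gray_min_mean")],
                      n_tips = ape::Ntip(tree),
                      package_version = as.character(
                        utils::packageVersion("ontocolor")),
                      schema = "ontocolor-report/1")),
    class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serialise the report: JSON of the statistics plus CSV tables.
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$color, file.path(dir, "contrast.csv"),
                   row.names = FALSE)
  js <- list(
    apparency_tests = lapply(report$apparency_tests, function(a) {
      if (!is.null(a$error)) return(list(error = a$error))
      list(W = a$w_statistic, p = a$p_value,
           pc_variance = as.numeric(a$variance_explained),
           n_apparent = a$n_apparent, n_nonapparent = a$n_nonapparent)
    }),
    pupa_match = if (!is.null(report$pupa_match))
      as.list(stats::setNames(report$pupa_match$p_value,
                              report$pupa_match$channel)),
    mk = lapply(report$mk, function(m) list(
      model = m$fit$model, rates = as.numeric(m$fit$rates),
      loglik = m$fit$loglik,
      modal_origins = lapply(m$origins, function(o) o$modal_count))),
    phyloglm = if (is.null(report$phyloglm$error)) list(
      coefficients = as.list(report$phyloglm$coefficients),
      z = as.list(report$phyloglm$z_scores),
      p = as.list(report$phyloglm$p_values),
      alpha = report$phyloglm$alpha) else report$phyloglm,
    predictor_correlation = if (is.null(report$predictor_correlation$error))
      report$predictor_correlation[c("z", "p_value", "r_squared")]
      else report$predictor_correlation,
    provenance = report$provenance)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (st in names(report$mk)) {
    utils::write.csv(map_segments(report$mk[[st]]$maps, 1L),
                     file.path(dir, sprintf("segments_%s.csv", st)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("ontocolor analysis report\n")
  for (st in names(x$apparency_tests)) {
    a <- x$apparency_tests[[st]]
    if (is.null(a$error))
      cat(sprintf("  %s instar apparency: W = %g, p = %.4g (PC1 %.1f%% var)\n",
                  st, a$w_statistic, a$p_value,
                  100 * a$variance_explained[1]))
  }
  if (!is.null(x$pupa_match))
    cat(sprintf("  pupa background match: p(R,G,B) = %s\n",
                paste(signif(x$pupa_match$p_value, 3), collapse = ", ")))
  for (st in names(x$mk))
    cat(sprintf("  %s: ER rate %.3g, modal origins apo/cry/masq = %d/%d/%d\n",
                st, x$mk[[st]]$fit$rates,
                x$mk[[st]]$origins$aposematism$modal_count,
                x$mk[[st]]$origins$crypsis$modal_count,
                x$mk[[st]]$origins$masquerade$modal_count))
  if (is.null(x$phyloglm$error)) {
    z <- x$phyloglm$z_scores
    cat(sprintf("  phyloglm apparency ~ vegetation + distribution: z = %s\n",
                paste(sprintf("%s %.3g", names(z), z), collapse = ", ")))
  }
  if (is.null(x$predictor_correlation$error))
    cat(sprintf("  toxicity~vegetation: z = %.3g, r^2 = %.3g\n",
                x$predictor_correlation$z, x$predictor_correlation$r_squared))
  invisible(x)
}
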