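# Phylogenetic logistic regression for a binary trait evolving on a tree
# (the evolving-binary-trait model of Ives & Garland), estimated by Firth-type
# penalized estimating equations with a phylogenetic working covariance.
#
# Model: tip i has P(y_i = 1) = p_i = logistic(x_i' beta); phylogenetic
# dependence enters through the working covariance
#   V = D^{1/2} R(alpha) D^{1/2},  D = diag(p_i (1 - p_i)),
#   R_ij = exp(-alpha * d_ij),     d_ij = patristic distance between tips,
# where alpha > 0 is the phylogenetic signal/attenuation parameter: small
# alpha means correlations persist across the tree, large alpha means the
# trait "forgets" its history and the model collapses to ordinary logistic
# regression. beta solves the Firth-penalized estimating equations; alpha
# maximizes the Gaussian pseudo-likelihood of the standardized residuals;
# the two steps alternate. With R = I the beta step reduces exactly to
# Firth logistic regression.

# Firth-penalized Newton solver for beta given the correlation inverse Rinv
# (NULL = identity). Returns list(beta, cov, iter, converged).
firth_newton <- function(X, y, Rinv = NULL, start = NULL,
                         max_iter = 200L, tol = 1e-10) {
  p <- ncol(X)
  beta <- start %||% numeric(p)
  conv <- FALSE
  score_at <- function(beta) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    v <- pmax(pr * (1 - pr), 1e-12)
    s <- sqrt(v)
    SX <- X * s
    if (is.null(Rinv)) {
      I <- crossprod(SX)
      RSX <- SX
      U0 <- drop(crossprod(X, y - pr))
    } else {
      RSX <- Rinv %*% SX
      I <- crossprod(SX, RSX)
      U0 <- drop(crossprod(RSX, (y - pr) / s))
    }
    Iinv <- solve(I + diag(1e-10, p))
    adj <- vapply(seq_len(p), function(r) {
      Xw <- X * (0.5 * s * (1 - 2 * pr) * X[, r])
      sum(Iinv * crossprod(Xw, RSX))  # tr(Iinv %*% t(Xw) %*% Rinv %*% SX)
    }, numeric(1))
    list(U = U0 + adj, I = I, Iinv = Iinv)
  }
  sc <- score_at(beta)
  for (it in seq_len(max_iter)) {
    step <- drop(sc$Iinv %*% sc$U)
    # step halving on the score norm
    lam <- 1
    for (h in 1:25) {
      cand <- beta + lam * step
      scc <- score_at(cand)
      if (max(abs(scc$U)) <= max(abs(sc$U)) + 1e-12 || max(abs(lam * step)) < tol)
        break
      lam <- lam / 2
    }
    beta <- cand
    moved <- max(abs(lam * step))
    sc <- scc
    if (moved < tol || max(abs(sc$U)) < 1e-8) { conv <- TRUE; break }
  }
  list(beta = beta, cov = sc$Iinv, iter = it, converged = conv,
       score = sc$U)
}

# Gaussian pseudo-log-likelihood of the standardized working residuals under
# R(alpha); profiled to estimate alpha jointly with the coefficients.
# Returns the negative log-likelihood. (A REML-style restriction term was
# evaluated and rejected: on degenerate distance structures such as star
# trees it biases alpha downward, inventing correlation in iid data.)
alpha_profile <- function(log_alpha, Dmat, e) {
  R <- exp(-exp(log_alpha) * Dmat)
  diag(R) <- 1
  ch <- tryCatch(chol(R + diag(1e-9, nrow(R))), error = function(err) NULL)
  if (is.null(ch)) return(1e10)
  z <- backsolve(ch, e, transpose = TRUE)
  sum(log(diag(ch))) + 0.5 * sum(z^2)
}

#' Phylogenetic logistic regression (penalized maximum likelihood)
#'
#' Fits a logistic regression of a binary trait on tip-level predictors while
#' accounting for phylogenetic non-independence under the evolving-binary-trait
#' model: tips that share recent ancestry have correlated states, with
#' correlation decaying as `exp(-alpha * patristic distance)`. Coefficients
#' and the signal parameter `alpha` are estimated jointly: a Firth-penalized
#' estimating-equation step for the coefficients (the penalization keeps
#' estimates finite under separation) alternates with a Gaussian
#' pseudo-likelihood profile step for `alpha` on its bounded range. On a
#' star phylogeny the estimator reduces to ordinary Firth-penalized logistic
#' regression.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param y named binary (0/1) vector over the tips; apparent = 1,
#'   nonapparent = 0 in the colour-defense application.
#' @param X predictor data.frame or matrix (rows = tips, in `tree$tip.label`
#'   order or named); factors are expanded via `model.matrix`. An intercept is
#'   added automatically.
#' @param alpha_bounds box constraint for `alpha`; default
#'   `c(1e-7, 50) / tree height`.
#' @param max_outer maximum alternations between the beta and alpha steps.
#' @return List of class `"phyloglm_fit"`: `coefficients`, `std_errors`,
#'   `z_scores`, `p_values` (two-sided normal), `alpha`, `converged`,
#'   `n`, `iterations`.
#' @export
fit_phyloglm <- function(tree, y, X, alpha_bounds = NULL, max_outer = 40L) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  if (!is.null(names(y))) {
    miss <- setdiff(tips, names(y))
    if (length(miss)) stop("response missing for tips: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    y <- y[tips]
  }
  y <- as.numeric(y)
  if (length(y) != length(tips)) stop("response length mismatch", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate response: needs both 0 and 1", call. = FALSE)

  if (is.data.frame(X)) {
    if (!is.null(rownames(X)) && all(tips %in% rownames(X)))
      X <- X[tips, , drop = FALSE]
    Xm <- stats::model.matrix(~ ., data = X)
  } else {
    Xm <- as.matrix(X)
    if (!is.null(rownames(Xm)) && all(tips %in% rownames(Xm)))
      Xm <- Xm[tips, , drop = FALSE]
    if (is.null(colnames(Xm)))
      colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
    Xm <- cbind(`(Intercept)` = 1, Xm)
  }
  if (nrow(Xm) != length(tips)) stop("predictor rows mismatch", call. = FALSE)
  if (qr(Xm)$rank < ncol(Xm))
    stop("predictors are rank deficient (constant or collinear column)",
         call. = FALSE)

  Dmat <- stats::cophenetic(tree)[tips, tips]
  h <- max(ape::node.depth.edgelength(tree)[seq_along(tips)])
  if (h <= 0) stop("tree height must be positive", call. = FALSE)
  ab <- alpha_bounds %||% (c(1e-7, 50) / h)

  rinv_at <- function(alpha) {
    R <- exp(-alpha * Dmat); diag(R) <- 1
    chol2inv(chol(R + diag(1e-9, nrow(R))))
  }
  prof_at <- function(la, beta) {
    pr <- stats::plogis(drop(Xm %*% beta))
    s <- sqrt(pmax(pr * (1 - pr), 1e-12))
    alpha_profile(la, Dmat, (y - pr) / s)
  }

  # joint estimation: alternate the penalized beta step with the restricted
  # profile for alpha, starting from the independence (Firth) solution
  fit <- firth_newton(Xm, y, Rinv = NULL)
  beta <- fit$beta
  alpha <- ab[2]
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    opt <- stats::optimize(function(la) prof_at(la, beta),
                           interval = log(ab), tol = 1e-6)
    alpha_new <- exp(opt$minimum)
    fit <- firth_newton(Xm, y, Rinv = rinv_at(alpha_new), start = beta)
    moved <- max(abs(fit$beta - beta))
    da <- abs(log(alpha_new) - log(alpha))
    beta <- fit$beta
    alpha <- alpha_new
    if (moved < 1e-8 && da < 1e-6) { converged <- fit$converged; break }
  }

  vcov <- fit$cov
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(z) <- names(pv) <- colnames(Xm)
  structure(list(coefficients = beta, std_errors = se, z_scores = z,
                 p_values = pv, alpha = alpha, alpha_bounds = ab,
                 converged = converged, n = length(y),
                 iterations = outer, vcov = vcov),
            class = "phyloglm_fit")
}

#' @export
print.phyloglm_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic logistic regression (MPLE), n = %d, alpha = %.4g%s\n",
              x$n, x$alpha, if (x$converged) "" else " [not converged]"))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors,
                    z = x$z_scores, p = x$p_values)
  print(signif(tab, 4))
  invisible(x)
}

#' Phylogenetic correlation test between two binary tip characters
#'
#' Regresses one binary character on the other with [fit_phyloglm()] and
#' reports the slope z-score and two-sided p-value, together with the ordinary
#' (non-phylogenetic) squared correlation of the two vectors as a descriptive
#' measure. Used to decide whether two predictors (e.g. host toxicity and
#' vegetation density) are too strongly associated to enter a model jointly.
#'
#' @param tree a rooted `phylo` object.
#' @param x,y named binary (0/1) vectors over the tips.
#' @return List: `z`, `p_value`, `r_squared`, `fit` (the underlying
#'   `"phyloglm_fit"`).
#' @export
predictor_correlation <- function(tree, x, y) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  if (!is.null(names(x))) x <- x[tips]
  if (!is.null(names(y))) y <- y[tips]
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("degenerate character vector", call. = FALSE)
  r2 <- stats::cor(x, y)^2
  fit <- fit_phyloglm(tree, stats::setNames(y, tips),
                      X = data.frame(x = x, row.names = tips))
  list(z = unname(fit$z_scores["x"]), p_value = unname(fit$p_values["x"]),
       r_squared = r2, fit = fit)
}
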