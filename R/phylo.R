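#' Read and validate a Newick chronogram
#'
#' Parses a Newick tree via `ape`, requiring branch lengths on every
#' edge, non-negative lengths and unique tip labels.
#'
#' @param path Path to a Newick file (or a Newick string containing
#'   `";"`).
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Lambda-scaled Brownian covariance matrix of a tree
#'
#' The Brownian-motion covariance of two tips is the shared root-to-MRCA
#' path length; under Pagel's lambda transform the off-diagonal entries
#' are multiplied by lambda while root-to-tip diagonals stay unscaled.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return Symmetric positive-semidefinite species x species matrix with
#'   tip labels as dimnames.
#' @export
bm_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  C <- ape::vcv(tree)
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

# profile log-likelihood of lambda: mu and sigma2 concentrated out by GLS
.lambda_loglik <- function(lambda, C0, diagC, y) {
  n <- length(y)
  C <- C0 * lambda
  diag(C) <- diagC
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  one <- rep(1, n)
  Ci_y <- backsolve(R, forwardsolve(t(R), y))
  Ci_1 <- backsolve(R, forwardsolve(t(R), one))
  mu <- sum(Ci_y) / sum(Ci_1)
  r <- y - mu
  q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  sigma2 <- q / n
  if (sigma2 <= 0) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdet / 2 - n / 2
}

#' Estimate Pagel's lambda for one trait
#'
#' Profile maximum likelihood over lambda in \[0, 1\]: for each lambda the
#' GLS mean and the ML Brownian rate are concentrated out in closed form
#' and the remaining 1-D likelihood is maximised by bounded optimisation
#' seeded from a coarse multistart grid. A likelihood-ratio test against
#' lambda = 0 uses the chi-square(1) reference (conservative at the
#' boundary; a 50:50 point-mass mixture p is also reported).
#'
#' @param tree A `phylo` tree (>= 4 tips analysed).
#' @param trait Named numeric vector (names = tip labels) or unnamed in
#'   tip order.
#' @param grid_n Multistart grid size, default 21.
#' @return List of class `lambda_estimate`: `lambda_hat`, `sigma2_hat`,
#'   `mu_hat`, `log_likelihood`, `loglik_lambda0`, `lrt_p_vs_zero`,
#'   `lrt_p_mixture`, `n`.
#' @export
estimate_lambda <- function(tree, trait, grid_n = 21) {
  C <- ape::vcv(tree)
  if (is.null(names(trait))) {
    stopifnot(length(trait) == nrow(C))
    names(trait) <- tree$tip.label
  }
  y <- trait[rownames(C)]
  if (anyNA(y)) stop("trait missing for tips: ",
                     paste(rownames(C)[is.na(y)], collapse = ", "))
  n <- length(y)
  if (n < 4) stop("need at least 4 species")
  if (stats::var(y) == 0) stop("trait has zero variance; lambda undefined")
  diagC <- diag(C)
  C0 <- C; diag(C0) <- 0
  f <- function(l) .lambda_loglik(l, C0, diagC, y)
  if (all(C0 == 0)) {                     # star phylogeny: likelihood flat
    lam <- 0
    ll <- f(0)
  } else {
    grid <- seq(0, 1, length.out = grid_n)
    gll <- vapply(grid, f, 0)
    best <- which.max(gll)
    lo <- grid[max(1, best - 1)]; hi <- grid[min(grid_n, best + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    lam <- opt$maximum; ll <- opt$objective
    for (b in c(0, 1)) if (f(b) >= ll) { lam <- b; ll <- f(b) }
  }
  # recover profiled mu, sigma2 at the optimum
  Ch <- C0 * lam; diag(Ch) <- diagC
  Ci <- solve(Ch)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  sigma2 <- as.numeric(t(y - mu) %*% Ci %*% (y - mu)) / n
  ll0 <- f(0)
  lrt <- max(0, 2 * (ll - ll0))
  p_chisq <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  p_mix <- if (lrt == 0) 1 else 0.5 * p_chisq
  structure(list(lambda_hat = lam, sigma2_hat = sigma2, mu_hat = mu,
                 log_likelihood = ll, loglik_lambda0 = ll0,
                 lrt_p_vs_zero = p_chisq, lrt_p_mixture = p_mix, n = n),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f (logL %.3f, LRT vs 0 p = %.4g, n = %d)\n",
              x$lambda_hat, x$log_likelihood, x$lrt_p_vs_zero, x$n))
  invisible(x)
}

#' Phylogenetic generalised least squares
#'
#' GLS regression of a species-mean trait on species-level predictors
#' with residual covariance `C(lambda)` from the tree. `lambda` may be a
#' fixed value in \[0, 1\] or `"ml"` for joint profile-ML estimation.
#'
#' @param tree A `phylo` tree.
#' @param y Named numeric response (names = tip labels).
#' @param X data.frame / matrix of predictors with rownames = tip labels,
#'   or a named vector for a single predictor; `NULL` fits the
#'   phylogenetic mean.
#' @param lambda Fixed value in \[0, 1\] or `"ml"`.
#' @return List of class `pgls_fit`: `coefficients` (term, estimate, se,
#'   t, p), `lambda`, `sigma2`, `log_likelihood`, `n`, `residuals`.
#' @export
pgls_fit <- function(tree, y, X = NULL, lambda = "ml") {
  C <- ape::vcv(tree)
  sp <- rownames(C)
  yv <- y[sp]
  if (anyNA(yv)) stop("response missing for some tips")
  n <- length(yv)
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(sp, "(Intercept)"))
  } else {
    if (is.null(dim(X))) X <- data.frame(x = X[sp], row.names = sp)
    Xm <- stats::model.matrix(~ ., data = as.data.frame(X)[sp, , drop = FALSE])
  }
  if (qr(Xm)$rank < ncol(Xm)) stop("predictor matrix is rank deficient")
  diagC <- diag(C); C0 <- C; diag(C0) <- 0
  gls_at <- function(l) {
    Cl <- C0 * l; diag(Cl) <- diagC
    R <- chol(Cl)
    Wy <- forwardsolve(t(R), yv)
    WX <- forwardsolve(t(R), Xm)
    fit <- stats::lm.fit(WX, Wy)
    r <- Wy - WX %*% fit$coefficients
    sigma2 <- sum(r^2) / n
    ll <- -n / 2 * log(2 * pi) - n / 2 * log(sigma2) -
      sum(log(diag(R))) - n / 2
    list(coef = fit$coefficients, sigma2 = sigma2, ll = ll, R = R)
  }
  if (identical(lambda, "ml")) {
    obj <- function(l) gls_at(l)$ll
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
    lam <- opt$maximum
    for (b in c(0, 1)) if (obj(b) >= opt$objective) lam <- b
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
  }
  g <- gls_at(lam)
  Cl <- C0 * lam; diag(Cl) <- diagC
  Ci <- solve(Cl)
  XtCiX <- t(Xm) %*% Ci %*% Xm
  p <- ncol(Xm)
  s2_unb <- g$sigma2 * n / max(1, n - p)
  vcov_b <- s2_unb * solve(XtCiX)
  se <- sqrt(diag(vcov_b))
  tval <- g$coef / se
  pval <- 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE)
  fitted <- as.numeric(Xm %*% g$coef)
  structure(list(
    coefficients = data.frame(term = colnames(Xm), estimate = as.numeric(g$coef),
                              se = se, t = as.numeric(tval), p = as.numeric(pval),
                              row.names = NULL, stringsAsFactors = FALSE),
    lambda = lam, sigma2 = g$sigma2, log_likelihood = g$ll, n = n,
    residuals = stats::setNames(yv - fitted, sp)),
    class = "pgls_fit")
}

#' Per-clade summaries and comparisons of behavioural indicators
#'
#' Summarises per-trial indicator values by clade (mean, SD, n) and, when
#' at least two clades have >= 2 trials, runs a Kruskal-Wallis test
#' across clades and Dunnett T3 pairwise comparisons.
#'
#' @param metrics data.frame of per-trial metrics including a `clade`
#'   column.
#' @param trait Indicator column name, default `"wf_distance_sl"`.
#' @return List of class `clade_summary`: `summary` (clade, n, mean, sd),
#'   `kruskal` (or NULL), `pairwise` (or NULL), `excluded` clades.
#' @export
clade_summaries <- function(metrics, trait = "wf_distance_sl") {
  stopifnot(trait %in% names(metrics), "clade" %in% names(metrics))
  m <- metrics[!is.na(metrics$clade), c("clade", trait)]
  counts <- table(m$clade)
  excluded <- names(counts)[counts < 2]
  if (length(excluded))
    warning("clades excluded from comparison (< 2 trials): ",
            paste(excluded, collapse = ", "))
  keep <- m$clade %in% names(counts)[counts >= 2]
  groups <- split(m[[trait]][keep], m$clade[keep])
  summ <- data.frame(clade = names(groups),
                     n = vapply(groups, length, 1L),
                     mean = vapply(groups, mean, 0),
                     sd = vapply(groups, stats::sd, 0),
                     row.names = NULL, stringsAsFactors = FALSE)
  summ <- summ[order(-summ$mean), ]
  kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
  pw <- if (length(groups) >= 2) dunnett_t3(groups) else NULL
  structure(list(summary = summ, kruskal = kw, pairwise = pw,
                 excluded = excluded, trait = trait),
            class = "clade_summary")
}

#' Species-mean trait table from per-trial metrics
#'
#' Aggregates per-trial indicator rows to species means, the unit of
#' analysis for phylogenetic-signal estimation.
#'
#' @param metrics data.frame with a `species` column and indicator
#'   columns.
#' @param traits Character vector of indicator columns to average.
#' @return data.frame: `species` plus one mean column per trait.
#' @export
species_trait_table <- function(metrics,
                                traits = c("wf_distance_sl", "wf_time_pct",
                                           "wf_frequency", "wf_speed_sl_s",
                                           "wf_max_speed_sl_s")) {
  traits <- intersect(traits, names(metrics))
  ag <- stats::aggregate(metrics[traits], by = list(species = metrics$species),
                         FUN = mean)
  ag
}
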