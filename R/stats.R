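#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Rank-based k-sample location test. Observations are mid-ranked across
#' groups; the statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \frac{N+1}{2})^2}
#' is divided by the tie-correction factor
#' \eqn{1 - \sum_g (t_g^3 - t_g) / (N^3 - N)} and referred to a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List of class `kruskal_result`: `H`, `df`, `p_value`,
#'   `tie_correction`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))$H  # 2.4
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0)) stop("all groups must be non-empty")
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  ni <- tabulate(g, k)
  rbar <- vapply(seq_len(k), function(i) mean(r[g == i]), 0)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tt <- table(x)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) {                      # all observations identical
    H <- 0; C <- 1
  } else {
    H <- H / C
  }
  structure(list(H = H, df = k - 1L,
                 p_value = stats::pchisq(H, k - 1, lower.tail = FALSE),
                 tie_correction = C, n = N),
            class = "kruskal_result")
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.4g, p = %.4g (tie correction %.4g)\n",
              x$df, x$H, x$p_value, x$tie_correction))
  invisible(x)
}

#' Dunnett's T3 all-pairs comparisons
#'
#' Pairwise Welch-type statistics with Satterthwaite degrees of freedom
#' for groups with unequal variances, adjusted for multiplicity over the
#' m = k(k-1)/2 comparisons with a studentized-maximum-modulus tail
#' evaluated under the independence approximation (equivalently a Sidak
#' correction of the two-sided Welch p-value).
#'
#' @param groups Named (or unnamed) list of >= 2 numeric vectors, each of
#'   length >= 2.
#' @return data.frame with one row per pair: `group_a, group_b,
#'   statistic, df, p_unadjusted, p_adjusted`.
#' @export
dunnett_t3 <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, stats::var, 0)
  ns <- vapply(groups, length, 1L)
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                    statistic = NA_real_, df = NA_real_,
                    p_unadjusted = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se2 <- vars[a] / ns[a] + vars[b] / ns[b]
    if (se2 == 0) {
      stat <- 0; df <- ns[a] + ns[b] - 2
    } else {
      stat <- (means[a] - means[b]) / sqrt(se2)
      df <- se2^2 / (vars[a]^2 / (ns[a]^2 * (ns[a] - 1)) +
                     vars[b]^2 / (ns[b]^2 * (ns[b] - 1)))
    }
    p <- if (se2 == 0) 1 else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    out$statistic[j] <- stat
    out$df[j] <- df
    out$p_unadjusted[j] <- p
    # SMM under independence: P(max |T| > q) = 1 - (2F(q) - 1)^m
    out$p_adjusted[j] <- 1 - (1 - p)^m
  }
  out
}

#' Second-order Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1), with k the number of
#' estimated parameters (including any dispersion parameter).
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value (Inf when n <= k + 1).
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a negative-binomial GLM (log link)
#'
#' Maximum-likelihood negative-binomial regression for over-dispersed
#' count responses, with joint estimation of the coefficients and the
#' NB size (dispersion) parameter. Predictors are standardized to unit
#' variance by default so coefficient magnitudes are comparable across
#' scales. Fitting delegates to [MASS::glm.nb()]; this wrapper adds
#' standardization, AICc and a uniform result container.
#'
#' @param response Non-negative integer response vector.
#' @param predictors data.frame (or NULL for intercept-only) of numeric
#'   predictors; factors are expanded by the usual model matrix rules.
#' @param standardize Scale numeric predictors to unit variance
#'   (default TRUE).
#' @param offset Optional log-scale offset vector.
#' @return List of class `nb_glm_fit`: `coefficients` (data.frame with
#'   `term, estimate, se`), `dispersion` (NB size), `log_likelihood`,
#'   `aicc`, `n`, `terms`, and the underlying `fit`.
#' @export
fit_negative_binomial_glm <- function(response, predictors = NULL,
                                      standardize = TRUE, offset = NULL) {
  if (any(response < 0) || any(response != round(response)))
    stop("response must be non-negative integers")
  if (all(response == 0)) stop("all-zero response: NB mean is degenerate")
  dat <- data.frame(.y = response)
  if (!is.null(predictors) && ncol(predictors) > 0) {
    pr <- as.data.frame(predictors)
    if (standardize)
      for (j in names(pr))
        if (is.numeric(pr[[j]]) && stats::sd(pr[[j]]) > 0)
          pr[[j]] <- as.numeric(scale(pr[[j]]))
    dat <- cbind(dat, pr)
    form <- stats::as.formula(paste(".y ~", paste(names(pr), collapse = " + ")))
  } else {
    form <- .y ~ 1
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) stop("negative-binomial fit failed to converge: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  n <- length(response)
  kpar <- nrow(cf) + 1                       # + dispersion
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    coefficients = data.frame(term = rownames(cf),
                              estimate = cf[, 1], se = cf[, 2],
                              row.names = NULL, stringsAsFactors = FALSE),
    dispersion = fit$theta,
    log_likelihood = ll,
    aicc = aicc(ll, kpar, n),
    n = n,
    terms = if (is.null(predictors)) character() else names(as.data.frame(predictors)),
    fit = fit),
    class = "nb_glm_fit")
}

#' AICc full model averaging over candidate predictor subsets
#'
#' Fits (or accepts) one model per candidate predictor subset, ranks them
#' by AICc, retains the set within `delta_max` of the best, computes
#' Akaike weights \eqn{w_i \propto \exp(-\Delta_i/2)} over the retained
#' set, and full-averages each coefficient: a model omitting a term
#' contributes 0 for its estimate. Adjusted standard errors follow the
#' standard multimodel formula
#' \eqn{SE_j = \sum_i w_i \sqrt{se_{ij}^2 + (\hat\beta_{ij} - \bar\beta_j)^2}};
#' 95% confidence intervals use the normal quantile, and terms whose CI
#' excludes 0 are flagged important.
#'
#' @param response Count response vector.
#' @param predictors data.frame of candidate predictors.
#' @param candidates List of character vectors naming predictor subsets;
#'   default all subsets (including the intercept-only model).
#' @param delta_max AICc retention threshold, default 2.
#' @param standardize Passed to [fit_negative_binomial_glm()].
#' @return List of class `model_average_result`: `candidate_models`
#'   (data.frame: model, k, aicc, delta_aicc, weight, retained),
#'   `averaged_coefficients` (term, estimate, adjusted_se, ci_lower,
#'   ci_upper, important), `importance` (per-term weight sums over the
#'   retained set), and `fits`.
#' @export
model_average_full <- function(response, predictors,
                               candidates = NULL, delta_max = 2,
                               standardize = TRUE) {
  pr <- as.data.frame(predictors)
  if (is.null(candidates)) {
    nm <- names(pr)
    candidates <- unlist(lapply(0:length(nm), function(m)
      utils::combn(nm, m, simplify = FALSE)), recursive = FALSE)
  }
  stopifnot(length(candidates) >= 1)
  n <- length(response)
  fits <- list(); labels <- character(); dropped <- character()
  for (cand in candidates) {
    lab <- if (length(cand)) paste(cand, collapse = "+") else "(intercept)"
    kpar <- length(cand) + 2            # intercept + dispersion
    if (n <= kpar + 1) {
      warning("candidate '", lab, "' dropped: n too small for AICc")
      dropped <- c(dropped, lab); next
    }
    f <- tryCatch(
      fit_negative_binomial_glm(response,
                                if (length(cand)) pr[cand] else NULL,
                                standardize = standardize),
      error = function(e) NULL)
    if (is.null(f)) {
      warning("candidate '", lab, "' dropped: NB fit did not converge")
      dropped <- c(dropped, lab); next
    }
    fits[[lab]] <- f
    labels <- c(labels, lab)
  }
  if (!length(fits)) stop("no fittable candidate models")
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  delta <- aiccs - min(aiccs)
  retained <- delta <= delta_max
  w <- exp(-delta[retained] / 2)
  w <- w / sum(w)
  weights <- numeric(length(fits)); weights[retained] <- w
  cand_df <- data.frame(model = labels,
                        k = vapply(fits, function(f) nrow(f$coefficients) + 1, 0),
                        aicc = aiccs, delta_aicc = delta,
                        weight = weights, retained = retained,
                        row.names = NULL, stringsAsFactors = FALSE)
  cand_df <- cand_df[order(cand_df$aicc), ]
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  avg <- data.frame(term = terms, estimate = 0, adjusted_se = 0,
                    stringsAsFactors = FALSE)
  importance <- stats::setNames(numeric(length(terms)), terms)
  ret_idx <- which(retained)
  for (ti in seq_along(terms)) {
    tm <- terms[ti]
    est <- se <- numeric(length(ret_idx))
    for (j in seq_along(ret_idx)) {
      cf <- fits[[ret_idx[j]]]$coefficients
      row <- match(tm, cf$term)
      if (!is.na(row)) {
        est[j] <- cf$estimate[row]; se[j] <- cf$se[row]
        importance[tm] <- importance[tm] + w[j]
      }                                  # absent -> 0 with se 0 (full average)
    }
    bbar <- sum(w * est)
    avg$estimate[ti] <- bbar
    avg$adjusted_se[ti] <- sum(w * sqrt(se^2 + (est - bbar)^2))
  }
  z <- stats::qnorm(0.975)
  avg$ci_lower <- avg$estimate - z * avg$adjusted_se
  avg$ci_upper <- avg$estimate + z * avg$adjusted_se
  avg$important <- avg$ci_lower > 0 | avg$ci_upper < 0
  structure(list(candidate_models = cand_df,
                 averaged_coefficients = avg,
                 importance = importance,
                 dropped = dropped,
                 fits = fits),
            class = "model_average_result")
}

#' @export
print.model_average_result <- function(x, ...) {
  cat(sprintf("AICc full model averaging: %d candidates, %d retained\n",
              nrow(x$candidate_models), sum(x$candidate_models$retained)))
  print(x$averaged_coefficients, digits = 4)
  invisible(x)
}
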