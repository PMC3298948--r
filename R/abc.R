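# Rejection/regression ABC machinery shared by the hierarchical co-divergence
# stage and the assemblage isolation-with-migration fit.

#' ABC rejection step
#'
#' Euclidean distance on summary statistics standardised by the
#' reference-table standard deviation (constant columns dropped); the
#' `n_accept` nearest rows are returned with Epanechnikov weights
#' `1 - (d/eps)^2` scaled to the acceptance radius `eps`.
#'
#' @param ref_stats numeric matrix of simulated summary statistics (rows =
#'   draws).
#' @param observed numeric vector of observed statistics, same layout as the
#'   columns of `ref_stats`.
#' @param n_accept number of draws to accept (must be < `nrow(ref_stats)`).
#' @return list with `idx` (accepted row indices), `dist`, `weights`,
#'   `eps` (acceptance radius), `sds` (standardisation), `kept` (columns
#'   used), `x_std` (accepted standardised statistics, centred at the
#'   observed point).
#' @export
abc_reject <- function(ref_stats, observed, n_accept) {
  ref_stats <- as.matrix(ref_stats)
  if (anyNA(observed)) {
    stop("NaN/NA in observed vector at position(s): ",
         paste(which(is.na(observed)), collapse = ", "))
  }
  if (length(observed) != ncol(ref_stats)) {
    stop("observed vector length (", length(observed),
         ") does not match reference statistics (", ncol(ref_stats), ")")
  }
  if (n_accept >= nrow(ref_stats)) {
    stop("n_accept must be smaller than the number of reference rows")
  }
  sds <- apply(ref_stats, 2, sd)
  kept <- which(sds > 0)
  if (length(kept) == 0) stop("all reference statistics are constant")
  z <- sweep(ref_stats[, kept, drop = FALSE], 2, observed[kept], "-")
  z <- sweep(z, 2, sds[kept], "/")
  d <- sqrt(rowSums(z * z))
  ord <- order(d)[seq_len(n_accept)]
  eps <- max(d[ord])
  w <- if (eps > 0) 1 - (d[ord] / eps)^2 else rep(1, n_accept)
  # zero weight at the boundary point degrades regression; keep a floor
  w <- pmax(w, 1e-8)
  list(idx = ord, dist = d[ord], weights = w, eps = eps, sds = sds,
       kept = kept, x_std = z[ord, , drop = FALSE])
}

# weighted quantile (type-7-like on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# mode via Gaussian KDE (Silverman bandwidth) on weighted draws
kde_mode <- function(x, w = NULL) {
  if (length(unique(x)) == 1 || diff(range(x)) < 1e-10 * (1 + max(abs(x))))
    return(stats::median(x))
  if (is.null(w)) w <- rep(1, length(x))
  d <- density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  d$x[which.max(d$y)]
}

#' Local-linear regression adjustment of a continuous parameter
#'
#' Beaumont-style adjustment: the parameter is transformed with
#' `log(x + eps_t)`, regressed (weighted, local-linear) on the standardised
#' accepted statistics centred at the observed point, the fit is projected to
#' the observed point, and draws are back-transformed, which keeps adjusted
#' values nonnegative. Falls back to the unadjusted accepted values with a
#' warning when the regression design is singular.
#'
#' @param param numeric vector of the parameter among accepted draws.
#' @param acc result of [abc_reject()] (at least 50 accepted draws advised).
#' @param eps_t transform offset (default 1e-6).
#' @return list with `adjusted` (draws), `mode`, `q025`, `median`, `q975`,
#'   `weights`, `adjusted_flag`.
#' @export
adjust_continuous <- function(param, acc, eps_t = 1e-6) {
  stopifnot(length(param) == length(acc$idx))
  y <- log(param + eps_t)
  X <- acc$x_std
  fit <- tryCatch({
    lm.wfit(cbind(1, X), y, acc$weights)
  }, error = function(e) NULL)
  adjusted_flag <- FALSE
  # aliased (NA) non-intercept coefficients are fine: lm.wfit drops exactly
  # collinear columns (e.g. net pi = dxy - (pi1+pi2)/2) and the fitted values
  # and residuals remain valid
  if (!is.null(fit) && !is.na(fit$coefficients[1])) {
    # value at the observed point (X = 0) plus residuals
    adj <- fit$coefficients[1] + fit$residuals
    adjusted_flag <- TRUE
  } else {
    warning("singular regression design; returning unadjusted draws")
    adj <- y
  }
  draws <- pmax(exp(adj) - eps_t, 0)
  q <- weighted_quantile(draws, acc$weights, c(0.025, 0.5, 0.975))
  list(adjusted = draws, mode = kde_mode(draws, acc$weights),
       q025 = q[1], median = q[2], q975 = q[3],
       weights = acc$weights, adjusted_flag = adjusted_flag)
}

#' Posterior for the number of co-divergence events (Psi)
#'
#' Weighted multinomial-logistic (polychotomous) regression of the Psi
#' category on the standardised accepted statistics, evaluated at the
#' observed point, with a small ridge penalty (`decay`) because accepted
#' samples are small relative to the summary dimension and separate easily;
#' falls back to weighted category frequencies when the fit fails. Both
#' versions are reported.
#'
#' @param psi integer vector of Psi among accepted draws.
#' @param acc result of [abc_reject()].
#' @param categories all Psi values with prior support (default
#'   `1:max(psi)`).
#' @param decay ridge (weight-decay) penalty of the multinomial fit.
#' @return list with `posterior` (regression-adjusted if available, over
#'   `categories`), `raw` (weighted frequencies), `mode`, `method`.
#' @export
estimate_psi <- function(psi, acc, categories = NULL, decay = 0.01) {
  stopifnot(length(psi) == length(acc$idx))
  if (is.null(categories)) categories <- seq_len(max(psi))
  w <- acc$weights
  raw <- vapply(categories, function(k) sum(w[psi == k]), numeric(1))
  raw <- raw / sum(raw)
  names(raw) <- categories
  present <- sort(unique(psi))
  post <- raw
  method <- "frequency"
  if (length(present) >= 2) {
    fit <- tryCatch({
      df <- data.frame(psi = factor(psi, levels = present), acc$x_std)
      capture_out <- utils::capture.output(
        m <- nnet::multinom(psi ~ ., data = df, weights = w, decay = decay,
                            trace = FALSE, maxit = 500, MaxNWts = 5000))
      nd <- as.data.frame(matrix(0, 1, ncol(acc$x_std)))
      names(nd) <- colnames(df)[-1]
      p <- predict(m, newdata = nd, type = "probs")
      if (is.null(dim(p))) p else p[1, ]
    }, error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit) && all(is.finite(fit))) {
      post <- setNames(numeric(length(categories)), categories)
      if (length(present) == 2) {
        # binary case: predict() returns P(second level)
        post[as.character(present)] <- c(1 - fit[1], fit[1])
      } else {
        post[names(fit)] <- fit
      }
      post <- pmax(post, 0)
      post <- post / sum(post)
      method <- "polychotomous_regression"
    }
  } else {
    warning("single Psi category among accepted draws; posterior is a point mass")
  }
  list(posterior = post, raw = raw,
       mode = as.integer(names(post)[which.max(post)]), method = method)
}

#' Bayes factor for a hypothesis pair
#'
#' `BF = [P(H1|D)/P(H2|D)] / [P(H1)/P(H2)]`, with a Jeffreys-scale label.
#' Zero posterior mass on H2 yields `+Inf` with the counts retained in the
#' result for context.
#'
#' @param post_p1,prior_p1 posterior and prior probability of H1 (H2 takes
#'   the complements).
#' @param hypothesis text label of the comparison.
#' @return list of class `bayes_factor`: `hypothesis`, `bf`,
#'   `interpretation`, `post_p1`, `prior_p1`.
#' @export
bayes_factor <- function(post_p1, prior_p1, hypothesis = "H1 vs H2") {
  stopifnot(prior_p1 > 0, prior_p1 < 1,
            post_p1 >= -1e-9, post_p1 <= 1 + 1e-9)
  post_p1 <- min(max(post_p1, 0), 1)
  bf <- if (post_p1 >= 1) Inf else
    (post_p1 / (1 - post_p1)) / (prior_p1 / (1 - prior_p1))
  structure(list(hypothesis = hypothesis, bf = bf,
                 interpretation = jeffreys_label(bf),
                 post_p1 = post_p1, prior_p1 = prior_p1),
            class = "bayes_factor")
}

#' Jeffreys-scale interpretation of a Bayes factor
#'
#' @param bf Bayes factor (>= 0).
#' @return character label.
#' @export
jeffreys_label <- function(bf) {
  if (is.na(bf)) return(NA_character_)
  if (bf < 1) return("negative (supports the alternative)")
  if (bf < 10^0.5) return("barely worth mentioning")
  if (bf < 10) return("substantial")
  if (bf < 10^1.5) return("strong")
  if (bf < 100) return("very strong")
  "decisive"
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF(%s) = %.4g [%s]\n", x$hypothesis, x$bf, x$interpretation))
  invisible(x)
}
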