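#' Buffer radius of a circle with a given area
#'
#' The pseudo-absence exclusion buffer is the radius of a circle whose area
#' equals the mean home range (99.7 km2 gives 5,633 m, rounded to 5,600 m).
#'
#' @param area_km2 circle area in km2.
#' @return list with `radius_m` (exact) and `rounded_m` (nearest 100 m).
#' @export
buffer_radius_from_area <- function(area_km2) {
  if (!is.numeric(area_km2) || area_km2 <= 0)
    stop("area must be a positive number")
  r <- sqrt(area_km2 * 1e6 / pi)
  list(radius_m = r, rounded_m = round(r / 100) * 100)
}

#' Generate pseudo-absence points outside presence buffers
#'
#' Uniform rejection sampling over the grid extent, discarding candidates
#' within `buffer_m` of any presence; produces `ratio` times as many points
#' as there are presences.
#'
#' @param presences `scape_points` of presences.
#' @param grid_geom [scape_grid] defining the sampling extent.
#' @param ratio pseudo-absences per presence (default 4).
#' @param buffer_m exclusion radius around each presence, meters.
#' @param seed RNG seed.
#' @param max_iter rejection-sampling cap (batches).
#' @return `scape_points` with role `pseudo_absence`.
#' @export
generate_pseudo_absences <- function(presences, grid_geom, ratio = 4,
                                     buffer_m, seed = 1, max_iter = 1000) {
  g <- grid_geom
  n_target <- round(ratio * nrow(presences))
  W <- ncol(g$values) * g$cellsize
  H <- nrow(g$values) * g$cellsize
  px <- presences$x; py <- presences$y
  set.seed(seed + 5)
  got_x <- numeric(0); got_y <- numeric(0)
  it <- 0
  b2 <- buffer_m^2
  while (length(got_x) < n_target) {
    it <- it + 1
    if (it > max_iter)
      stop(sprintf(paste0("pseudo-absence sampling exhausted %d iterations ",
                          "(free area too small); attained %d of %d"),
                   max_iter, length(got_x), n_target))
    m <- max(2L * (n_target - length(got_x)), 100L)
    cx <- stats::runif(m, g$xll, g$xll + W)
    cy <- stats::runif(m, g$yll, g$yll + H)
    if (buffer_m <= 0) {
      keep <- rep(TRUE, m)
    } else {
      # min squared distance to any presence, chunked over presences
      mind <- rep(Inf, m)
      step <- 2000L
      for (s0 in seq(1L, length(px), by = step)) {
        s1 <- min(s0 + step - 1L, length(px))
        d2 <- outer(cx, px[s0:s1], "-")^2 + outer(cy, py[s0:s1], "-")^2
        mind <- pmin(mind, do.call(pmin, as.data.frame(d2)))
      }
      keep <- mind >= b2
    }
    got_x <- c(got_x, cx[keep]); got_y <- c(got_y, cy[keep])
  }
  scape_points(id = paste0("a", seq_len(n_target)),
               x = got_x[seq_len(n_target)], y = got_y[seq_len(n_target)],
               role = "pseudo_absence")
}

#' Assemble a use-availability data frame
#'
#' Binds presences (response 1) and pseudo-absences (response 0) with their
#' covariate values extracted from a (scaled) stack; rows with any missing
#' covariate are dropped.
#'
#' @param presences,absences `scape_points`.
#' @param stack scaled `covariate_stack`.
#' @return data.frame with column `use` plus one column per layer.
#' @export
use_availability_data <- function(presences, absences, stack) {
  d1 <- stack_extract(stack, presences)
  d0 <- stack_extract(stack, absences)
  d <- rbind(cbind(use = 1, d1), cbind(use = 0, d0))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Second-order AIC
#'
#' `AICc = -2 LL + 2k + 2k(k+1)/(n-k-1)`; requires `n > k + 1`.
#'
#' @param LL log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @export
aicc <- function(LL, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: n must exceed k + 1")
  -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta vector of AICc differences from the best model.
#' @return weights `exp(-delta/2) / sum(exp(-delta/2))`.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit a use-availability logistic regression
#'
#' Maximum-likelihood binomial GLM with logit link of presence (1) versus
#' pseudo-absence (0) on the named covariates. Errors on rank-deficient
#' designs and on perfect separation (named after the separating term).
#'
#' @param data data.frame from [use_availability_data] (column `use` plus
#'   covariates).
#' @param terms character vector of covariate names (empty for the null
#'   model).
#' @return object of class `pop_rsf` with elements `fit` (the glm), `terms`,
#'   `coef`, `LL`, `k`, `n`, `AICc`.
#' @export
fit_logistic <- function(data, terms = character(0)) {
  stopifnot("use" %in% names(data))
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("use ~", rhs))
  X <- stats::model.matrix(f, data)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix; drop collinear terms")
  fit <- suppressWarnings(stats::glm(f, data = data,
                                     family = stats::binomial()))
  if (!fit$converged) stop("logistic fit did not converge")
  p <- stats::fitted(fit)
  if (length(terms) && all(p[data$use == 1] > 1 - 1e-8) &&
      all(p[data$use == 0] < 1e-8)) {
    sep <- terms[which.max(abs(stats::coef(fit)[terms]))]
    stop("perfect separation detected; separating term: ", sep)
  }
  LL <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  n <- nrow(data)
  structure(list(fit = fit, terms = terms, coef = stats::coef(fit),
                 LL = LL, k = k, n = n, AICc = aicc(LL, k, n),
                 label = rhs),
            class = "pop_rsf")
}

#' @export
print.pop_rsf <- function(x, ...) {
  cat("<pop_rsf> use ~", x$label, "\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$LL, x$AICc))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
coef.pop_rsf <- function(object, ...) object$coef

#' @export
logLik.pop_rsf <- function(object, ...) {
  structure(object$LL, df = object$k, class = "logLik")
}

#' Rank a candidate model set by AICc
#'
#' @param models list of `pop_rsf` fits, or a data.frame with columns `LL`,
#'   `k`, `n` (e.g. a published model-selection table).
#' @return data.frame ordered by AICc with `delta` and Akaike `weight`
#'   columns (weights sum to 1).
#' @export
rank_models <- function(models) {
  if (is.data.frame(models)) {
    tab <- data.frame(model = if (!is.null(models$model)) models$model
                              else paste0("m", seq_len(nrow(models))),
                      k = models$k, LL = models$LL, n = models$n)
  } else {
    tab <- data.frame(model = vapply(models, function(m) m$label, ""),
                      k = vapply(models, function(m) m$k, 0),
                      LL = vapply(models, function(m) m$LL, 0),
                      n = vapply(models, function(m) m$n, 0))
  }
  tab$AICc <- aicc(tab$LL, tab$k, tab$n)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$delta <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$delta)
  rownames(tab) <- NULL
  tab
}

#' Predict a suitability map from a fitted model
#'
#' @param object a `pop_rsf` fit.
#' @param stack scaled `covariate_stack` (same layer names used in fitting).
#' @param ... unused.
#' @return [scape_grid] of predicted selection probability.
#' @export
predict.pop_rsf <- function(object, stack, ...) {
  g1 <- stack$layers[[1]]
  nd <- as.data.frame(lapply(stack$layers,
                             function(g) as.vector(grid_values(g))))
  p <- rep(NA_real_, nrow(nd))
  ok <- stats::complete.cases(nd[object$terms])
  if (length(object$terms) == 0) ok <- rep(TRUE, nrow(nd))
  p[ok] <- stats::predict(object$fit, newdata = nd[ok, , drop = FALSE],
                          type = "response")
  grid_like(g1, matrix(p, nrow(g1$values), ncol(g1$values)))
}

#' Model-averaged suitability prediction
#'
#' Retains models within `delta_cutoff` AICc units of the best model,
#' renormalizes their Akaike weights, and averages the per-cell predicted
#' probabilities: `H = sum(w_m * p_m)`, bounded by the member predictions.
#'
#' @param models list of `pop_rsf` fits.
#' @param stack scaled `covariate_stack`.
#' @param delta_cutoff AICc window (default 2).
#' @return list with `suitability` ([scape_grid] `H` in `[0,1]`), `table`
#'   (the full ranking), and `retained` (model labels averaged).
#' @export
model_average_predict <- function(models, stack, delta_cutoff = 2) {
  tab <- rank_models(models)
  labs <- vapply(models, function(m) m$label, "")
  keep_labs <- tab$model[tab$delta <= delta_cutoff]
  keep <- models[match(keep_labs, labs)]
  w <- akaike_weights(tab$delta[tab$delta <= delta_cutoff])
  g1 <- stack$layers[[1]]
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (i in seq_along(keep))
    acc <- acc + w[i] * grid_values(stats::predict(keep[[i]], stack))
  list(suitability = grid_like(g1, acc), table = tab, retained = keep_labs)
}

#' Rank-statistic AUC of the ROC curve
#'
#' Mann-Whitney AUC with tie correction: midranks of the positive scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated k-fold (95/5) cross-validated classification accuracy
#'
#' Trains the logistic model on a random `train_frac` subset and scores
#' classification accuracy (probability threshold 0.5) on the held-out
#' fraction, repeated `reps` times; splits lacking both classes in training
#' are redrawn.
#'
#' @param data use-availability data.frame.
#' @param terms covariate names.
#' @param train_frac training fraction (default 0.95).
#' @param reps repetitions (default 1000).
#' @param seed RNG seed.
#' @param threshold classification threshold (default 0.5).
#' @return list with `mean_accuracy` and `accuracy` (per-rep vector).
#' @export
kfold_accuracy <- function(data, terms, train_frac = 0.95, reps = 1000,
                           seed = 1, threshold = 0.5) {
  n <- nrow(data)
  n_train <- round(train_frac * n)
  if (n_train < 2 || n_train >= n)
    stop("too few points to split at this training fraction")
  set.seed(seed + 6)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("use ~", rhs))
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    repeat {
      tr <- sample.int(n, n_train)
      if (length(unique(data$use[tr])) == 2) break
    }
    fit <- suppressWarnings(stats::glm(f, data = data[tr, ],
                                       family = stats::binomial()))
    p <- stats::predict(fit, newdata = data[-tr, ], type = "response")
    acc[r] <- mean((p > threshold) == (data$use[-tr] == 1))
  }
  list(mean_accuracy = mean(acc), accuracy = acc)
}
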