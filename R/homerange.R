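#' Filter telemetry to resident individuals with enough fixes
#'
#' Individuals with `min_fixes` or fewer fixes, and individuals flagged as
#' dispersers, are removed (a 30-fix threshold keeps animals with >30 fixes,
#' i.e. at least 31).
#'
#' @param telemetry `scape_points` with `individual_id`.
#' @param min_fixes keep individuals with strictly more fixes than this
#'   (default 30).
#' @param exclude character vector of disperser individual ids to drop.
#' @return filtered `scape_points`; attribute `removals` is a data.frame of
#'   dropped individuals with the reason.
#' @export
filter_individuals <- function(telemetry, min_fixes = 30,
                               exclude = character(0)) {
  stopifnot("individual_id" %in% names(telemetry))
  counts <- table(telemetry$individual_id)
  few <- names(counts)[counts <= min_fixes]
  removals <- rbind(
    if (length(few)) data.frame(individual_id = few, reason = "few_fixes"),
    if (length(exclude)) data.frame(individual_id = exclude,
                                    reason = "disperser"))
  drop <- unique(c(few, exclude))
  out <- telemetry[!telemetry$individual_id %in% drop, , drop = FALSE]
  if (!nrow(out)) stop("no individuals left after filtering")
  attr(out, "removals") <- removals
  out
}

#' Kernel density home range (95% isopleth)
#'
#' Bivariate product-Gaussian KDE with per-axis reference bandwidth
#' `h = sd * n^(-1/6)`, evaluated on a grid extending 4 bandwidths beyond
#' the fix hull. The isopleth is the smallest set of cells whose density
#' mass reaches the target (so its mass is within one cell's mass above it);
#' the home-range area is the cell count times cell area.
#'
#' @param fixes `scape_points` (or data.frame with `x`, `y`) for one
#'   individual; >= 5 fixes unless `bandwidth` is supplied.
#' @param isopleth density mass contained (default 0.95).
#' @param bandwidth optional bandwidth override (length 1 or 2, meters).
#' @param grid_n minimum grid resolution per axis (default 200).
#' @return object of class `home_range`: `mask` (0/1 [scape_grid]),
#'   `density`, `area_km2`, `bandwidth`, `n_fixes`, `iso_mass`.
#' @export
kde_home_range <- function(fixes, isopleth = 0.95, bandwidth = NULL,
                           grid_n = 200) {
  x <- fixes$x; y <- fixes$y
  n <- length(x)
  if (is.null(bandwidth)) {
    if (n < 5) stop("need >= 5 fixes to estimate a bandwidth")
    hx <- stats::sd(x) * n^(-1 / 6)
    hy <- stats::sd(y) * n^(-1 / 6)
    if (!is.finite(hx) || !is.finite(hy) || hx == 0 || hy == 0)
      stop("degenerate fixes (zero spread): cannot estimate bandwidth")
  } else {
    bandwidth <- rep_len(bandwidth, 2)
    hx <- bandwidth[1]; hy <- bandwidth[2]
    if (hx <= 0 || hy <= 0) stop("bandwidth must be positive")
  }
  x0 <- min(x) - 4 * hx; x1 <- max(x) + 4 * hx
  y0 <- min(y) - 4 * hy; y1 <- max(y) + 4 * hy
  cell <- max((x1 - x0), (y1 - y0)) / grid_n
  nc <- max(2L, ceiling((x1 - x0) / cell))
  nr <- max(2L, ceiling((y1 - y0) / cell))
  gx <- x0 + (seq_len(nc) - 0.5) * cell
  gy <- y0 + (seq_len(nr) - 0.5) * cell
  phx <- outer(gx, x, function(g, xi) stats::dnorm((g - xi) / hx))
  phy <- outer(gy, y, function(g, yi) stats::dnorm((g - yi) / hy))
  dens <- (phy %*% t(phx)) / (n * hx * hy)  # rows = y (south-first)
  mass <- dens * cell^2
  mass <- mass / sum(mass)
  o <- order(mass, decreasing = TRUE)
  cm <- cumsum(mass[o])
  ncell <- which(cm >= isopleth)[1]
  mask <- matrix(0, nr, nc)
  mask[o[seq_len(ncell)]] <- 1
  g <- scape_grid(mask, cell, x0, y0, nodata = -9999)
  structure(list(mask = g,
                 density = scape_grid(dens, cell, x0, y0),
                 area_km2 = ncell * (cell / 1000)^2,
                 bandwidth = c(hx = hx, hy = hy), n_fixes = n,
                 iso_mass = cm[ncell], isopleth = isopleth),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %d fixes, %.0f%% isopleth, area %.2f km2\n",
              x$n_fixes, 100 * x$isopleth, x$area_km2))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based k-sample comparison with tie correction; the statistic is
#' referred to a chi-square with (groups - 1) df. Thin wrapper over
#' [stats::kruskal.test] returning the pieces used downstream.
#'
#' @param values numeric response (e.g. home-range areas).
#' @param groups group labels (e.g. sex).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Uniform availability sample within a home range
#'
#' Samples points uniformly over the cells of the 95% isopleth mask (uniform
#' cell choice, uniform position within the cell). The number of points
#' matches the individual's fix count in the study design.
#'
#' @param hr a `home_range`.
#' @param n number of points.
#' @param seed RNG seed.
#' @return `scape_points` with role `available`.
#' @export
sample_availability <- function(hr, n, seed = 1) {
  m <- hr$mask
  idx <- which(m$values == 1)
  if (!length(idx)) stop("empty home-range mask")
  set.seed(seed + 7)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  rc <- arrayInd(pick, dim(m$values))
  s <- m$cellsize
  scape_points(id = paste0("av", seq_len(n)),
               x = m$xll + (rc[, 2] - 1) * s + stats::runif(n) * s,
               y = m$yll + (rc[, 1] - 1) * s + stats::runif(n) * s,
               role = "available")
}

#' Consistent AIC
#'
#' `CAIC = -2 LL + k (ln n + 1)`; penalizes parameters more strongly than
#' AIC for n >= 8.
#'
#' @param LL log-likelihood.
#' @param k parameter count.
#' @param n sample size.
#' @export
caic <- function(LL, k, n) -2 * LL + k * (log(n) + 1)

#' Fit a use-availability RSF within home ranges
#'
#' Estimates selection coefficients from pooled used (1) and available (0)
#' points across individuals via a weighted binomial GLM. The
#' `distribution` weighting gives every animal equal total weight
#' (`w = N / (I * n_i)` for each of individual i's `n_i` rows, `I` animals,
#' `N` rows in total), so the fit is not dominated by heavily-collared
#' animals; `none` is the pooled unweighted fit. The `exponential_RSF` form
#' scores relative selection `exp(beta' x)` (intercept absorbed); the
#' `logistic_RSPF` form returns absolute selection probabilities.
#'
#' @param used,available `scape_points` with `individual_id` (each
#'   individual must appear in both).
#' @param stack scaled `covariate_stack`.
#' @param terms covariate names (default: all stack layers).
#' @param form `exponential_RSF` or `logistic_RSPF`.
#' @param weighting `distribution` or `none`.
#' @return object of class `rsf_fit` with `coef`, `se`, `LL` (weighted
#'   binomial log-likelihood), `k`, `n`, `CAIC`, `form`, `weighting`.
#' @export
fit_weighted_rsf <- function(used, available, stack,
                             terms = names(stack$layers),
                             form = c("exponential_RSF", "logistic_RSPF"),
                             weighting = c("distribution", "none")) {
  form <- match.arg(form)
  weighting <- match.arg(weighting)
  iu <- unique(used$individual_id)
  ia <- unique(available$individual_id)
  if (length(setdiff(iu, ia)))
    stop("individual(s) lacking available points: ",
         paste(setdiff(iu, ia), collapse = ", "))
  du <- cbind(use = 1, stack_extract(stack, used),
              individual_id = used$individual_id)
  da <- cbind(use = 0, stack_extract(stack, available),
              individual_id = available$individual_id)
  d <- rbind(du, da)
  d <- d[stats::complete.cases(d[terms]), , drop = FALSE]
  n <- nrow(d)
  w <- if (weighting == "distribution") {
    ni <- table(d$individual_id)
    as.numeric(n / (length(ni) * ni[d$individual_id]))
  } else rep(1, n)
  fit_rsf_data(d, terms, w, form, weighting)
}

# core weighted logistic fit on a prepared use/availability data.frame
fit_rsf_data <- function(d, terms, w, form, weighting) {
  f <- stats::as.formula(paste("use ~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, d)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  d$.w <- w
  fit <- suppressWarnings(stats::glm(f, data = d, weights = .w,
                                     family = stats::binomial(),
                                     control = list(epsilon = 1e-12,
                                                    maxit = 100)))
  if (!fit$converged) stop("weighted RSF fit did not converge")
  co <- stats::coef(fit)
  p <- stats::fitted(fit)
  if (all(p[d$use == 1] > 1 - 1e-8) && all(p[d$use == 0] < 1e-8))
    stop("perfect separation detected; separating term: ",
         terms[which.max(abs(co[terms]))])
  y <- d$use
  LL <- sum(w * (y * log(pmax(p, 1e-300)) +
                 (1 - y) * log(pmax(1 - p, 1e-300))))
  k <- length(co)
  n <- nrow(d)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(fit = fit, terms = terms, coef = co, se = se,
                 LL = LL, k = k, n = n, CAIC = caic(LL, k, n),
                 form = form, weighting = weighting),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %s (%s weighting): n = %d, k = %d\n",
              x$form, x$weighting, x$n, x$k))
  cat(sprintf("  logLik = %.3f, CAIC = %.3f\n", x$LL, x$CAIC))
  print(data.frame(coef = round(x$coef, 4), se = round(x$se, 4)))
  invisible(x)
}

#' @export
coef.rsf_fit <- function(object, ...) object$coef

#' Predict from a fitted RSF
#'
#' @param object an `rsf_fit`.
#' @param newdata data.frame of covariates.
#' @param type `response` (fitted probability of the use-availability
#'   surrogate / RSPF probability), `link`, or `rsf` (relative selection
#'   `exp(beta' x)` without the intercept).
#' @param ... unused.
#' @export
predict.rsf_fit <- function(object, newdata,
                            type = c("response", "link", "rsf"), ...) {
  type <- match.arg(type)
  eta <- stats::predict(object$fit, newdata = newdata, type = "link")
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         rsf = exp(eta - object$coef[1]))
}

#' Compare RSF forms (or weighting schemes) by consistent AIC
#'
#' @param fits named list of `rsf_fit` objects on the same data.
#' @return list with `choice` (name of the lowest-CAIC fit) and `table`.
#' @export
compare_forms <- function(fits) {
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1)
    stop("fits compared by CAIC must use the same data (n differs)")
  tab <- data.frame(model = names(fits),
                    form = vapply(fits, function(f) f$form, ""),
                    LL = vapply(fits, function(f) f$LL, 0),
                    k = vapply(fits, function(f) f$k, 0),
                    CAIC = vapply(fits, function(f) f$CAIC, 0))
  tab <- tab[order(tab$CAIC), ]
  rownames(tab) <- NULL
  list(choice = tab$model[1], table = tab)
}

#' Relative-selection-strength use curve
#'
#' The use-probability graph: fitted values of the RSF/RSPF at *available*
#' locations plotted against one covariate, with a local-regression smooth
#' (span 0.75, degree 1) through the points. Because fitted use averages
#' over the availability of the other covariates, the curve changes when
#' that availability changes; it depicts probability of use, not of
#' selection.
#'
#' @param fit an `rsf_fit`.
#' @param available_data data.frame of covariates at available points
#'   (must contain every model term).
#' @param covariate_name covariate to display on the x axis.
#' @param span loess span (default 0.75).
#' @return data.frame with `x`, `fitted`, `smooth`, ordered by `x`.
#' @export
rss_use_curve <- function(fit, available_data, covariate_name, span = 0.75) {
  if (!covariate_name %in% names(available_data))
    stop("covariate absent from available data: ", covariate_name)
  miss <- setdiff(fit$terms, names(available_data))
  if (length(miss))
    stop("available data lacks model term(s): ", paste(miss, collapse = ", "))
  p <- stats::predict(fit, newdata = available_data, type = "response")
  x <- available_data[[covariate_name]]
  o <- order(x)
  sm <- if (length(unique(x)) > 3) {
    lo <- stats::loess(p ~ x, span = span, degree = 1,
                       family = "gaussian")
    stats::predict(lo, newdata = data.frame(x = x[o]))
  } else rep(mean(p), length(x))
  data.frame(x = x[o], fitted = p[o], smooth = sm)
}
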