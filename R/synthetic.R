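#' Synthetic landscape configuration
#'
#' Describes the synthetic study system: a multi-class land-cover mosaic with
#' spatial autocorrelation (emulating a 30 m categorical land-cover product),
#' linear road features in two traffic classes, and streams. Class
#' proportions must sum to 1.
#'
#' @param nrow,ncol grid extent in cells.
#' @param cellsize cell edge, meters (default 30, the resolution of the
#'   land-cover product the generator emulates).
#' @param classes character vector of land-cover class names.
#' @param proportions target class proportions (same length, sums to 1).
#' @param autocorr_range Gaussian smoothing range in cells controlling patch
#'   size (default 8).
#' @param n_high_traffic,n_other_road,n_stream counts of linear features.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(nrow = 200, ncol = 200, cellsize = 30,
                             classes = c("forest", "crop", "pasture",
                                         "herbaceous", "shrub", "developed",
                                         "water"),
                             proportions = c(0.35, 0.25, 0.12, 0.10, 0.05,
                                             0.10, 0.03),
                             autocorr_range = 8,
                             n_high_traffic = 2, n_other_road = 4,
                             n_stream = 3) {
  if (length(classes) != length(proportions))
    stop("classes and proportions must have equal length")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be nonnegative and sum to 1")
  if (nrow < 1 || ncol < 1) stop("extent must be positive")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize,
                 classes = classes, proportions = proportions,
                 autocorr_range = autocorr_range,
                 n_high_traffic = n_high_traffic,
                 n_other_road = n_other_road, n_stream = n_stream),
            class = "landscape_config")
}

#' Ground-truth selection model for synthetic data
#'
#' Holds the generative selection coefficients used for parameter-recovery
#' testing. Population-level presences are sampled with cell weights
#' `plogis(intercept + beta %*% x)` over scaled covariates; the default
#' intercept of -12 keeps selection deep in the rare-event regime where the
#' inverse-logit weight is numerically proportional to `exp(beta %*% x)`
#' (relative distortion below 0.1% over the default coefficient range), so
#' the use-availability logistic slope estimand equals `beta`.
#'
#' @param beta named numeric vector of selection coefficients; names must
#'   match covariate-stack layer names.
#' @param intercept generative intercept on the logit scale (default -12).
#' @param availability_ratio pseudo-absences per presence (default 4).
#' @param hr_sigma home-range dispersion (bivariate normal SD, meters) for
#'   telemetry generation (default 900 m).
#' @param ind_beta named coefficients of the individual-level exponential
#'   thinning RSF (defaults to `beta`).
#' @param disperser_preference exponent concentrating dispersers on
#'   high-current cells (default 2; 0 = uniform).
#' @return a `truth_model` list.
#' @export
truth_model <- function(beta, intercept = -12, availability_ratio = 4,
                        hr_sigma = 900, ind_beta = beta,
                        disperser_preference = 2) {
  stopifnot(is.numeric(beta), !is.null(names(beta)), all(is.finite(beta)))
  if (availability_ratio <= 0) stop("availability ratio must be > 0")
  structure(list(beta = beta, intercept = intercept,
                 availability_ratio = availability_ratio,
                 hr_sigma = hr_sigma, ind_beta = ind_beta,
                 disperser_preference = disperser_preference),
            class = "truth_model")
}

# Smoothed Gaussian random field (circular FFT convolution with a Gaussian
# kernel of SD = range cells). Draws from the current RNG stream.
gaussian_field <- function(nr, nc, range) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range <= 0) return(z)
  dx <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  dy <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  k <- outer(exp(-dy^2 / (2 * range^2)), exp(-dx^2 / (2 * range^2)))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (nr * nc)
  sm
}

#' Generate a categorical land-cover grid
#'
#' Thresholds a smoothed Gaussian random field at quantiles matching the
#' target class proportions, which yields spatially autocorrelated patches
#' with realized proportions equal to the targets up to quantile ties.
#' Classes are coded 1..K in the order of `config$classes`.
#'
#' @param config a [landscape_config].
#' @param seed RNG seed (fixed seed implies an identical grid).
#' @return a [scape_grid] of integer class codes, with attribute `classes`.
#' @export
generate_landcover <- function(config, seed = 1) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed)
  f <- gaussian_field(config$nrow, config$ncol, config$autocorr_range)
  # rank-transform so quantile thresholds give exact proportions
  r <- matrix(rank(f, ties.method = "first"), config$nrow, config$ncol)
  cum <- cumsum(config$proportions)
  n <- length(r)
  breaks <- c(0, round(cum * n))
  breaks[length(breaks)] <- n
  cls <- matrix(cut(r, breaks = breaks, labels = FALSE),
                config$nrow, config$ncol)
  g <- scape_grid(cls, config$cellsize)
  attr(g, "classes") <- config$classes
  g
}

#' Generate road and stream polylines
#'
#' Each feature runs from one edge of the extent to the opposite edge with
#' mild random jitter, emulating through-going roads and streams.
#'
#' @param config a [landscape_config].
#' @param seed RNG seed.
#' @return a `scape_lines` object.
#' @export
generate_lines <- function(config, seed = 1) {
  stopifnot(inherits(config, "landscape_config"))
  W <- config$ncol * config$cellsize
  H <- config$nrow * config$cellsize
  if (W <= 0 || H <= 0) stop("zero extent")
  set.seed(seed + 1)
  make_line <- function(class) {
    vertical <- stats::runif(1) < 0.5
    nv <- 8
    if (vertical) {
      x0 <- stats::runif(1, 0.1 * W, 0.9 * W)
      y <- seq(0, H, length.out = nv)
      x <- pmin(pmax(x0 + cumsum(c(0, stats::rnorm(nv - 1, 0, 0.03 * W))),
                     0), W - 1e-6)
      coords <- cbind(x, pmin(y, H - 1e-6))
    } else {
      y0 <- stats::runif(1, 0.1 * H, 0.9 * H)
      x <- seq(0, W, length.out = nv)
      y <- pmin(pmax(y0 + cumsum(c(0, stats::rnorm(nv - 1, 0, 0.03 * H))),
                     0), H - 1e-6)
      coords <- cbind(pmin(x, W - 1e-6), y)
    }
    list(coords = coords, class = class)
  }
  feats <- c(
    lapply(seq_len(config$n_high_traffic), function(i) make_line("high_traffic")),
    lapply(seq_len(config$n_other_road), function(i) make_line("other_road")),
    lapply(seq_len(config$n_stream), function(i) make_line("stream")))
  scape_lines(feats)
}

# cell-level selection weights plogis(b0 + X beta) from a covariate stack
truth_weights <- function(stack, truth, link = c("logit", "log")) {
  link <- match.arg(link)
  nms <- names(truth$beta)
  miss <- setdiff(nms, names(stack$layers))
  if (length(miss))
    stop("covariate stack lacks layer(s): ", paste(miss, collapse = ", "))
  eta <- truth$intercept
  for (nm in nms) eta <- eta + truth$beta[[nm]] * grid_values(stack$layers[[nm]])
  w <- if (link == "logit") stats::plogis(eta) else exp(eta)
  w[is.na(w)] <- 0
  w
}

#' Generate presence points from a known selection surface
#'
#' Samples `n` presence cells (with replacement) with probability
#' proportional to `plogis(intercept + beta' x)` over the scaled covariate
#' stack, then places each point uniformly within its cell — an inhomogeneous
#' point process on the lattice matching the use-availability logistic
#' structure.
#'
#' @param stack a covariate stack (see [build_covariates]) containing every
#'   layer named in `truth$beta`, already scaled.
#' @param truth a [truth_model].
#' @param n number of presences.
#' @param seed RNG seed.
#' @return `scape_points` with role `presence`.
#' @export
generate_presences <- function(stack, truth, n, seed = 1) {
  g <- stack$layers[[1]]
  w <- truth_weights(stack, truth)
  if (all(w <= 0)) stop("degenerate truth model: all selection weights zero")
  set.seed(seed + 2)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  s <- g$cellsize
  x <- g$xll + (rc[, 2] - 1) * s + stats::runif(n) * s
  y <- g$yll + (rc[, 1] - 1) * s + stats::runif(n) * s
  scape_points(id = paste0("p", seq_len(n)), x = x, y = y, role = "presence")
}

#' Generate per-individual GPS telemetry with exponential-RSF thinning
#'
#' Each individual gets a home-range center; candidate fixes are drawn from a
#' bivariate normal kernel around the center and retained with probability
#' proportional to `exp(ind_beta' x)` (rejection sampling against the
#' landscape maximum), emulating within-home-range selection. Individuals
#' alternate sex F/M and are split between two study areas (west half =
#' "southern", east half = "eastern").
#'
#' @param stack scaled covariate stack with the layers named in
#'   `truth$ind_beta`.
#' @param truth a [truth_model].
#' @param n_individuals number of animals.
#' @param fixes_per_individual single count or vector (may vary 31-630 to
#'   emulate collar variability).
#' @param seed RNG seed.
#' @return `scape_points` with role `telemetry` and columns `individual_id`,
#'   `sex`, `study_area`.
#' @export
generate_telemetry <- function(stack, truth, n_individuals,
                               fixes_per_individual, seed = 1) {
  if (any(fixes_per_individual < 1)) stop("fixes per individual must be >= 1")
  fx <- rep_len(fixes_per_individual, n_individuals)
  g <- stack$layers[[1]]
  w <- truth_weights(stack, truth_model(truth$ind_beta, intercept = 0),
                     link = "log")
  wmax <- max(w)
  W <- ncol(g$values) * g$cellsize
  H <- nrow(g$values) * g$cellsize
  set.seed(seed + 3)
  sig <- truth$hr_sigma
  res <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    cx <- stats::runif(1, g$xll + 0.2 * W, g$xll + 0.8 * W)
    cy <- stats::runif(1, g$yll + 0.2 * H, g$yll + 0.8 * H)
    got_x <- numeric(0); got_y <- numeric(0)
    tries <- 0
    while (length(got_x) < fx[i]) {
      m <- 4 * (fx[i] - length(got_x)) + 20
      px <- stats::rnorm(m, cx, sig)
      py <- stats::rnorm(m, cy, sig)
      val <- extract_at(grid_like(g, w), px, py)
      keep <- !is.na(val) & stats::runif(m) < val / wmax
      got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
      tries <- tries + 1
      if (tries > 2000) stop("telemetry thinning failed to accept enough fixes")
    }
    res[[i]] <- data.frame(x = got_x[seq_len(fx[i])], y = got_y[seq_len(fx[i])],
                           individual_id = sprintf("ind%02d", i),
                           sex = if (i %% 2) "F" else "M",
                           study_area = if (cx - g$xll < W / 2) "southern"
                                        else "eastern")
  }
  df <- do.call(rbind, res)
  scape_points(id = paste0("t", seq_len(nrow(df))), x = df$x, y = df$y,
               role = "telemetry", individual_id = df$individual_id,
               sex = df$sex, study_area = df$study_area)
}

#' Generate candidate disperser locations from a current map
#'
#' Samples `n` cells with probability proportional to
#' `current ^ preference`; `preference = 0` gives a spatially uniform draw
#' over valid cells, larger values concentrate points in high-current
#' corridors.
#'
#' @param current_map a [scape_grid] of nonnegative current density.
#' @param n number of points.
#' @param preference concentration exponent (>= 0).
#' @param seed RNG seed.
#' @return `scape_points` with role `disperser`.
#' @export
generate_dispersers <- function(current_map, n, preference = 2, seed = 1) {
  v <- grid_values(current_map)
  if (any(v < 0, na.rm = TRUE)) stop("current map must be nonnegative")
  w <- v^preference
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all-zero current map: cannot sample dispersers")
  set.seed(seed + 4)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  s <- current_map$cellsize
  x <- current_map$xll + (rc[, 2] - 1) * s + stats::runif(n) * s
  y <- current_map$yll + (rc[, 1] - 1) * s + stats::runif(n) * s
  scape_points(id = paste0("d", seq_len(n)), x = x, y = y, role = "disperser")
}
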