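#' Build matched used/available sets around disperser locations
#'
#' For each disperser location (the 1's), draws `n_avail` random points
#' uniformly within a disc of `buffer_m` (the 0's) and extracts the quantile
#' bin (1-10) of every candidate connectivity map at all points. Locations
#' whose disc cannot yield points on classified cells are dropped and
#' reported.
#'
#' @param dispersers `scape_points` of candidate disperser locations.
#' @param decile_maps named list of decile grids (from [quantile_classify]),
#'   one per candidate resistance-suitability relationship.
#' @param buffer_m disc radius for availability (default 5000 m).
#' @param n_avail available points per location (default 3).
#' @param seed RNG seed.
#' @return data.frame with `location_id`, `used` (1/0), `x`, `y`, and one
#'   `decile_<map>` column per map; attribute `dropped` lists dropped
#'   location ids.
#' @export
build_matched_sets <- function(dispersers, decile_maps, buffer_m = 5000,
                               n_avail = 3, seed = 1) {
  stopifnot(length(decile_maps) >= 1, !is.null(names(decile_maps)))
  set.seed(seed + 8)
  rows <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(dispersers))) {
    ux <- dispersers$x[i]; uy <- dispersers$y[i]
    udec <- vapply(decile_maps, function(m) extract_at(m, ux, uy), 0)
    if (any(is.na(udec))) { dropped <- c(dropped, dispersers$id[i]); next }
    ax <- numeric(0); ay <- numeric(0)
    tries <- 0
    while (length(ax) < n_avail && tries < 200) {
      tries <- tries + 1
      m <- 4 * (n_avail - length(ax))
      rr <- buffer_m * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      cx <- ux + rr * cos(th); cy <- uy + rr * sin(th)
      dec <- sapply(decile_maps, function(g) extract_at(g, cx, cy))
      dec <- matrix(dec, nrow = m)
      ok <- apply(!is.na(dec), 1, all)
      ax <- c(ax, cx[ok]); ay <- c(ay, cy[ok])
    }
    if (length(ax) < n_avail) { dropped <- c(dropped, dispersers$id[i]); next }
    ax <- ax[seq_len(n_avail)]; ay <- ay[seq_len(n_avail)]
    px <- c(ux, ax); py <- c(uy, ay)
    rec <- data.frame(location_id = dispersers$id[i],
                      used = c(1, rep(0, n_avail)), x = px, y = py)
    for (nm in names(decile_maps))
      rec[[paste0("decile_", nm)]] <- extract_at(decile_maps[[nm]], px, py)
    rows[[length(rows) + 1]] <- rec
  }
  if (!length(rows)) stop("no disperser locations could be matched")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(dropped))
    message(length(dropped), " location(s) dropped (disc outside map): ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Mixed-effects logistic model of disperser use on a map's deciles
#'
#' Random-intercept (per location) logistic regression of used (1) versus
#' available (0) on the quantile bin of one connectivity map, estimated by
#' Laplace approximation. `k = 3` (intercept, decile slope, random-intercept
#' variance); AICc uses the number of observations.
#'
#' @param matched data.frame from [build_matched_sets].
#' @param map_name name of the map whose `decile_<map_name>` column is the
#'   fixed effect.
#' @param nAGQ adaptive Gauss-Hermite quadrature points (1 = Laplace).
#' @return object of class `map_glmm` with `slope`, `LL`, `k`, `n`, `AICc`.
#' @export
fit_mixed_logistic <- function(matched, map_name, nAGQ = 1) {
  col <- paste0("decile_", map_name)
  if (!col %in% names(matched)) stop("no decile column for map: ", map_name)
  d <- data.frame(used = matched$used, decile = matched[[col]],
                  loc = factor(matched$location_id))
  if (length(unique(d$decile)) < 2)
    stop("no decile variation; model is unidentifiable")
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(used ~ decile + (1 | loc), data = d,
                family = stats::binomial(), nAGQ = nAGQ)))
  LL <- as.numeric(stats::logLik(fit))
  n <- nrow(d)
  k <- 3L
  structure(list(fit = fit, map = map_name,
                 slope = unname(lme4::fixef(fit)["decile"]),
                 LL = LL, k = k, n = n, AICc = aicc(LL, k, n)),
            class = "map_glmm")
}

#' @export
print.map_glmm <- function(x, ...) {
  cat(sprintf("<map_glmm> map '%s': decile slope %.4f, logLik %.3f, AICc %.2f\n",
              x$map, x$slope, x$LL, x$AICc))
  invisible(x)
}

#' Rank connectivity maps by AICc and produce the weighted-average map
#'
#' Akaike weights are computed from the three mixed-model AICc values; each
#' current map is normalized to unit mean over valid cells (the raw maps
#' have incomparable scales) and averaged with those weights.
#'
#' @param fits named list of `map_glmm` fits (names match `maps`).
#' @param maps named list of current [scape_grid]s sharing geometry.
#' @return list with `table` (model-selection table with `delta` and
#'   `weight`), `weights` (named), `averaged` ([scape_grid]).
#' @export
rank_and_average_maps <- function(fits, maps) {
  stopifnot(all(names(fits) %in% names(maps)))
  g1 <- maps[[1]]
  for (m in maps) check_same_geometry(g1, m)
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$k, 0),
                    LL = vapply(fits, function(f) f$LL, 0),
                    AICc = vapply(fits, function(f) f$AICc, 0))
  tab <- tab[order(tab$AICc), ]
  tab$delta <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$delta)
  rownames(tab) <- NULL
  w <- stats::setNames(tab$weight, tab$model)
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (nm in names(maps)) {
    v <- grid_values(maps[[nm]])
    v <- v / mean(v, na.rm = TRUE)
    v[is.na(v)] <- 0
    acc <- acc + w[[nm]] * v
  }
  acc[is.na(grid_values(g1))] <- NA_real_
  list(table = tab, weights = w, averaged = grid_like(g1, acc))
}
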