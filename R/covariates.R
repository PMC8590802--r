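#' Covariate stack
#'
#' A named collection of co-registered covariate grids plus (after
#' [scale_covariates]) the per-layer mean/SD used for scaling, so predictions
#' on new data can reuse the training scaling.
#'
#' @param layers named list of [scape_grid] objects sharing geometry.
#' @param scaling optional data.frame with columns `name`, `mean`, `sd`.
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, scaling = NULL) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  g1 <- layers[[1]]
  for (g in layers) check_same_geometry(g1, g)
  structure(list(layers = layers, scaling = scaling),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat("<covariate_stack>", length(x$layers), "layers:",
      paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$scaling)) cat("  scaled (mean/SD stored)\n")
  invisible(x)
}

#' Window edge in cells for a square moving window
#'
#' The window is square with edge `sqrt(area)` (a 7 km2 window has edge
#' 2.64 km), converted to cells and rounded to the nearest odd count so the
#' window centers on a cell.
#'
#' @param window_area_km2 window area in km2.
#' @param cellsize cell edge in meters.
#' @return odd integer edge length in cells.
#' @export
window_edge_cells <- function(window_area_km2, cellsize) {
  if (window_area_km2 <= 0) stop("window area must be positive")
  edge_m <- sqrt(window_area_km2) * 1000
  k <- 2L * as.integer(round((edge_m / cellsize - 1) / 2)) + 1L
  if (k < 1L) stop("window smaller than one cell")
  k
}

# padded 2-D cumulative sum; NA treated as 0
cumsum2 <- function(M) {
  M[is.na(M)] <- 0
  S <- apply(M, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  rbind(0, cbind(0, S))
}

# box-filter sum over a (2h+1)-edge window truncated at the grid boundary
box_sum <- function(M, h) {
  nr <- nrow(M); nc <- ncol(M)
  S <- cumsum2(M)
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Moving-window class proportion
#'
#' For each cell, the fraction of non-nodata cells within the square window
#' that belong to `class`. Windows are truncated at the grid boundary and
#' proportions computed over the available cells.
#'
#' @param landcover categorical [scape_grid] (integer class codes; attribute
#'   `classes` maps names to codes).
#' @param class class name (if the grid carries a `classes` attribute) or
#'   integer code.
#' @param window_area_km2 window area in km2 (edge = sqrt(area)).
#' @return [scape_grid] of proportions in `[0, 1]`.
#' @export
window_proportion <- function(landcover, class, window_area_km2) {
  v <- grid_values(landcover)
  if (is.character(class)) {
    cls <- attr(landcover, "classes")
    if (is.null(cls) || !class %in% cls)
      stop("unknown class name: ", class)
    class <- match(class, cls)
  }
  k <- window_edge_cells(window_area_km2, landcover$cellsize)
  h <- (k - 1L) / 2L
  ind <- (v == class) * 1
  valid <- (!is.na(v)) * 1
  num <- box_sum(ind, h)
  den <- box_sum(valid, h)
  p <- ifelse(den > 0, num / den, NA_real_)
  grid_like(landcover, p)
}

# Felzenszwalb & Huttenlocher 1-D squared distance transform.
# f: squared distances (may contain BIG for "no source"); returns lower
# envelope of parabolas.
.dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact Euclidean distance transform (meters, center-to-center) from a
# logical source matrix
distance_transform <- function(src, cellsize) {
  BIG <- 1e12
  f <- ifelse(src, 0, BIG)
  nr <- nrow(f); nc <- ncol(f)
  for (j in seq_len(nc)) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- .dt1d(f[i, ])
  sqrt(f) * cellsize
}

#' Rasterize polylines to per-cell line length
#'
#' Exact parametric clipping of each segment against the cell lattice; the
#' returned grid holds meters of line per cell.
#'
#' @param lines a `scape_lines` object.
#' @param grid_geom a [scape_grid] supplying geometry.
#' @param classes optional subset of line classes to include.
#' @return [scape_grid] of line length (m) per cell.
#' @export
rasterize_lines <- function(lines, grid_geom, classes = NULL) {
  g <- grid_geom
  s <- g$cellsize
  nr <- nrow(g$values); nc <- ncol(g$values)
  len <- matrix(0, nr, nc)
  xs <- g$xll + (0:nc) * s
  ys <- g$yll + (0:nr) * s
  for (f in lines$features) {
    if (!is.null(classes) && !f$class %in% classes) next
    cc <- f$coords
    for (i in seq_len(nrow(cc) - 1)) {
      x1 <- cc[i, 1]; y1 <- cc[i, 2]; x2 <- cc[i + 1, 1]; y2 <- cc[i + 1, 2]
      L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      if (L == 0) next
      tx <- if (x2 != x1) (xs - x1) / (x2 - x1) else numeric(0)
      ty <- if (y2 != y1) (ys - y1) / (y2 - y1) else numeric(0)
      ts <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
      for (m in seq_len(length(ts) - 1)) {
        t0 <- ts[m]; t1 <- ts[m + 1]
        tm <- (t0 + t1) / 2
        px <- x1 + tm * (x2 - x1); py <- y1 + tm * (y2 - y1)
        ci <- floor((px - g$xll) / s) + 1
        ri <- floor((py - g$yll) / s) + 1
        if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc)
          len[ri, ci] <- len[ri, ci] + L * (t1 - t0)
      }
    }
  }
  grid_like(g, len)
}

#' Euclidean distance to nearest line feature (or source cells)
#'
#' Exact center-to-nearest-rasterized-feature Euclidean distance transform.
#'
#' @param source a `scape_lines` object, or a logical matrix / [scape_grid]
#'   of source cells.
#' @param grid_geom a [scape_grid] supplying geometry.
#' @param classes optional line-class filter (e.g. `"high_traffic"`).
#' @return [scape_grid] of distances in meters.
#' @export
distance_to <- function(source, grid_geom, classes = NULL) {
  g <- grid_geom
  if (inherits(source, "scape_lines")) {
    len <- grid_values(rasterize_lines(source, g, classes))
    src <- !is.na(len) & len > 0
  } else if (is.scape_grid(source)) {
    src <- !is.na(grid_values(source)) & grid_values(source) > 0
  } else {
    src <- source
  }
  if (!any(src)) stop("empty source set: no features intersect the grid")
  d <- distance_transform(src, g$cellsize)
  grid_like(g, d)
}

#' Road density (km of road per km2) in a moving window
#'
#' Rasterizes roads to per-cell length, then divides the windowed total
#' length by the in-grid window area (truncated at the boundary).
#'
#' @param lines a `scape_lines` object.
#' @param grid_geom a [scape_grid] supplying geometry.
#' @param window_area_km2 window area in km2.
#' @param classes road classes counted (default both road classes).
#' @return [scape_grid] of km/km2.
#' @export
road_density <- function(lines, grid_geom, window_area_km2,
                         classes = c("high_traffic", "other_road")) {
  g <- grid_geom
  len_km <- grid_values(rasterize_lines(lines, g, classes)) / 1000
  k <- window_edge_cells(window_area_km2, g$cellsize)
  h <- (k - 1L) / 2L
  tot <- box_sum(len_km, h)
  ncell <- box_sum(matrix(1, nrow(len_km), ncol(len_km)), h)
  area_km2 <- ncell * (g$cellsize / 1000)^2
  grid_like(g, tot / area_km2)
}

#' Build the standard covariate stack from a landscape
#'
#' Moving-window land-cover proportions at the requested scales, distance to
#' high-traffic roads, distance to all roads, distance to streams, and road
#' density. Layer names follow `<class>_<area>km2` (e.g. `forest_50km2`).
#'
#' @param landcover categorical [scape_grid] with a `classes` attribute.
#' @param lines a `scape_lines` object.
#' @param scales_km2 window areas (default `c(7, 15, 30, 50)`).
#' @param prop_classes land-cover classes to summarize (default forest,
#'   pasture, herbaceous).
#' @param density_window_km2 window for road density (default 7).
#' @return an unscaled `covariate_stack`.
#' @export
build_covariates <- function(landcover, lines,
                             scales_km2 = c(7, 15, 30, 50),
                             prop_classes = c("forest", "pasture",
                                              "herbaceous"),
                             density_window_km2 = 7) {
  layers <- list()
  for (cl in prop_classes)
    for (a in scales_km2)
      layers[[sprintf("%s_%gkm2", cl, a)]] <-
        window_proportion(landcover, cl, a)
  layers[["dist_main_roads"]] <- distance_to(lines, landcover, "high_traffic")
  layers[["dist_all_roads"]] <-
    distance_to(lines, landcover, c("high_traffic", "other_road"))
  layers[["dist_streams"]] <- distance_to(lines, landcover, "stream")
  layers[["road_density"]] <-
    road_density(lines, landcover, density_window_km2)
  covariate_stack(layers)
}

#' Center and scale a covariate stack
#'
#' Each layer is transformed to `(x - mean) / sd` over non-nodata cells; the
#' means and SDs are retained in the stack so the identical scaling can be
#' applied to new data via the `scaling` argument.
#'
#' @param stack a `covariate_stack`.
#' @param scaling optional previously stored scaling data.frame; if supplied
#'   it is applied instead of recomputing.
#' @return scaled `covariate_stack` with `scaling` populated.
#' @export
scale_covariates <- function(stack, scaling = NULL) {
  nms <- names(stack$layers)
  if (is.null(scaling)) {
    mu <- sd <- numeric(length(nms))
    for (i in seq_along(nms)) {
      v <- grid_values(stack$layers[[i]])
      mu[i] <- mean(v, na.rm = TRUE)
      sd[i] <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(sd[i]) || sd[i] == 0)
        stop("constant covariate cannot be scaled: ", nms[i])
    }
    scaling <- data.frame(name = nms, mean = mu, sd = sd)
  } else {
    if (!all(nms %in% scaling$name))
      stop("stored scaling lacks some layers")
  }
  layers <- stack$layers
  for (i in seq_along(nms)) {
    row <- scaling[scaling$name == nms[i], ]
    v <- (grid_values(layers[[i]]) - row$mean) / row$sd
    layers[[i]] <- grid_like(layers[[i]], v)
  }
  covariate_stack(layers, scaling)
}

#' Pairwise Pearson correlation screen
#'
#' Computes all pairwise Pearson correlations over shared non-nodata cells
#' and flags pairs exceeding the threshold, the standard pre-modeling screen
#' used to drop collinear covariates.
#'
#' @param stack a `covariate_stack` with >= 2 layers.
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @return list with `correlations` (matrix) and `flagged` (data.frame of
#'   pairs with `|r| > threshold`).
#' @export
correlation_screen <- function(stack, threshold = 0.7) {
  nms <- names(stack$layers)
  if (length(nms) < 2) stop("need at least two covariates to screen")
  X <- sapply(stack$layers, function(g) as.vector(grid_values(g)))
  R <- stats::cor(X, use = "pairwise.complete.obs")
  idx <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  flagged <- data.frame(var1 = nms[idx[, 1]], var2 = nms[idx[, 2]],
                        r = R[idx])
  list(correlations = R, flagged = flagged)
}

#' Extract covariate values at points
#'
#' @param stack a `covariate_stack`.
#' @param pts a `scape_points` data.frame.
#' @return data.frame, one column per layer.
#' @export
stack_extract <- function(stack, pts) {
  out <- lapply(stack$layers, function(g) extract_at(g, pts$x, pts$y))
  as.data.frame(out)
}
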