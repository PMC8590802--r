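#' Suitability-to-resistance transform specification
#'
#' The exponential-decay family maps suitability `H` in `[0,1]` to
#' resistance `R = 100 - 99 * (1 - exp(-c H)) / (1 - exp(-c))`, so `R(0) =
#' 100` and `R(1) = 1` for every exponent `c`; larger `c` makes resistance
#' drop faster at low suitability. The linear transform uses the same
#' `[1, 100]` range: `R = 100 - 99 H`.
#'
#' @param kind `linear` or `exponential`.
#' @param c shape exponent for the exponential kind (2 = intermediate,
#'   8 = sharp drop at low suitability).
#' @return object of class `resistance_transform`.
#' @export
resistance_transform <- function(kind = c("exponential", "linear"), c = 2) {
  kind <- match.arg(kind)
  if (kind == "exponential" && c == 0)
    stop("c = 0 is degenerate for the exponential transform; use linear")
  structure(list(kind = kind, c = c), class = "resistance_transform")
}

#' Transform a suitability grid to a resistance grid
#'
#' Suitability values outside `[0, 1]` are clipped with a warning. Output is
#' strictly decreasing in `H`, with `R(0) = 100` and `R(1) = 1`.
#'
#' @param H_grid [scape_grid] of suitability in `[0, 1]` (or a bare numeric
#'   vector, transformed directly).
#' @param transform a [resistance_transform].
#' @return resistance grid (or numeric vector) in `[1, 100]`.
#' @export
suitability_to_resistance <- function(H_grid, transform) {
  stopifnot(inherits(transform, "resistance_transform"))
  H <- if (is.scape_grid(H_grid)) grid_values(H_grid) else H_grid
  if (any(H < -1e-12 | H > 1 + 1e-12, na.rm = TRUE))
    warning("suitability values outside [0,1] clipped")
  H <- pmin(pmax(H, 0), 1)
  R <- if (transform$kind == "linear") 100 - 99 * H
       else 100 - 99 * (1 - exp(-transform$c * H)) / (1 - exp(-transform$c))
  if (is.scape_grid(H_grid)) grid_like(H_grid, R) else R
}

#' Build the conductance graph of a resistance grid
#'
#' One node per valid (non-nodata) cell; edges connect 4- or 8-neighbors
#' with conductance equal to the arithmetic mean of the two cells'
#' conductances `1/R`, diagonal edges scaled by `1/sqrt(2)` (the
#' average-conductance convention of circuit-theory connectivity software).
#'
#' @param R_grid resistance [scape_grid] (values >= 1 at valid cells).
#' @param neighborhood 8 (default) or 4.
#' @return object of class `scape_graph`: `edges` (data.frame `i`, `j`,
#'   `cond`), `n` nodes, `node_id` (matrix mapping cells to node index, NA at
#'   nodata), `grid` (geometry reference).
#' @export
grid_to_graph <- function(R_grid, neighborhood = 8) {
  stopifnot(neighborhood %in% c(4, 8))
  R <- grid_values(R_grid)
  valid <- !is.na(R)
  if (!any(valid)) stop("all-nodata grid: no graph nodes")
  nr <- nrow(R); nc <- ncol(R)
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[valid] <- seq_len(sum(valid))
  g <- 1 / R
  edge_block <- function(dr, dc, scale) {
    r0 <- seq_len(nr - abs(dr)) + max(0, -dr)
    c0 <- seq_len(nc - abs(dc)) + max(0, -dc)
    a <- node_id[r0, c0, drop = FALSE]
    b <- node_id[r0 + dr, c0 + dc, drop = FALSE]
    ca <- g[r0, c0, drop = FALSE]
    cb <- g[r0 + dr, c0 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    data.frame(i = a[ok], j = b[ok],
               cond = scale * 0.5 * (ca[ok] + cb[ok]))
  }
  blocks <- list(edge_block(0, 1, 1), edge_block(1, 0, 1))
  if (neighborhood == 8) {
    blocks <- c(blocks, list(edge_block(1, 1, 1 / sqrt(2)),
                             edge_block(1, -1, 1 / sqrt(2))))
  }
  structure(list(edges = do.call(rbind, blocks), n = sum(valid),
                 node_id = node_id, grid = R_grid),
            class = "scape_graph")
}

#' @export
print.scape_graph <- function(x, ...) {
  cat("<scape_graph>", x$n, "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# node indices of a region mask (logical matrix or 0/1 scape_grid)
region_nodes <- function(graph, region) {
  m <- if (is.scape_grid(region)) grid_values(region) > 0 else region
  ids <- graph$node_id[which(m)]
  ids <- ids[!is.na(ids)]
  if (!length(ids)) stop("region does not intersect any valid cell")
  ids
}

# connected-component labels via union-find on the edge list
graph_components <- function(graph) {
  parent <- seq_len(graph$n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(nrow(graph$edges))) {
    ra <- find(graph$edges$i[r]); rb <- find(graph$edges$j[r])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(graph$n), find, 0L)
}

#' Pairwise current flow between two node regions
#'
#' Contracts each region to a super-node, injects unit current at region A
#' and grounds region B, and solves the graph Laplacian for node potentials.
#' Returns the per-cell current density (half the sum of absolute currents
#' on incident edges; region cells carry the full current they pass into the
#' network) and the effective resistance (potential difference per unit
#' current).
#'
#' @param graph a `scape_graph`.
#' @param region_A,region_B disjoint region masks (0/1 [scape_grid] or
#'   logical matrix).
#' @return list with `current` ([scape_grid]), `effective_resistance`,
#'   `potentials` (per node).
#' @export
solve_pair <- function(graph, region_A, region_B) {
  idA <- region_nodes(graph, region_A)
  idB <- region_nodes(graph, region_B)
  if (length(intersect(idA, idB))) stop("node regions must be disjoint")
  comp <- graph_components(graph)
  if (!any(comp[idA] %in% comp[idB]))
    stop(sprintf(paste0("regions are in different connected components ",
                        "(A in %s; B in %s)"),
                 paste(unique(comp[idA]), collapse = ","),
                 paste(unique(comp[idB]), collapse = ",")))
  # contraction map: region members share a super-node index
  map <- seq_len(graph$n)
  a_new <- min(idA); b_new <- min(idB)
  map[idA] <- a_new
  map[idB] <- b_new
  keep <- sort(unique(map))
  remap <- integer(graph$n)
  remap[keep] <- seq_along(keep)
  map <- remap[map]
  a_new <- remap[a_new]; b_new <- remap[b_new]
  e <- graph$edges
  mi <- map[e$i]; mj <- map[e$j]
  off <- mi != mj
  n2 <- length(keep)
  L <- Matrix::sparseMatrix(
    i = c(mi[off], mj[off]), j = c(mj[off], mi[off]),
    x = -c(e$cond[off], e$cond[off]), dims = c(n2, n2))
  deg <- -Matrix::rowSums(L)
  L <- L + Matrix::Diagonal(n2, deg)
  free <- setdiff(seq_len(n2), b_new)
  rhs <- numeric(n2); rhs[a_new] <- 1
  Lff <- Matrix::forceSymmetric(L[free, free, drop = FALSE])
  vfree <- as.numeric(Matrix::solve(Matrix::Cholesky(Lff, LDL = FALSE),
                                    rhs[free], system = "A"))
  v2 <- numeric(n2)
  v2[free] <- vfree
  v <- v2[map]  # potential per original node
  # per-edge currents and per-cell current density
  icur <- e$cond * (v[e$i] - v[e$j])
  inA <- seq_len(graph$n) %in% idA
  inB <- seq_len(graph$n) %in% idB
  same_region <- (inA[e$i] & inA[e$j]) | (inB[e$i] & inB[e$j])
  half <- 0.5 * abs(icur) * !same_region
  sums <- rowsum(c(half, half), c(e$i, e$j))
  node_cur <- numeric(graph$n)
  node_cur[as.integer(rownames(sums))] <- sums[, 1]
  # region cells carry the full current they inject/collect
  node_cur[inA | inB] <- 2 * node_cur[inA | inB]
  cur <- matrix(NA_real_, nrow(graph$node_id), ncol(graph$node_id))
  cur[!is.na(graph$node_id)] <- node_cur[graph$node_id[!is.na(graph$node_id)]]
  list(current = grid_like(graph$grid, cur),
       effective_resistance = v2[a_new] - v2[b_new],
       potentials = v)
}

#' Cumulative current map over all region pairs
#'
#' Sums the per-cell current of [solve_pair] over every unordered pair of
#' node regions (10 pairs for 5 regions). Failing pairs are reported and
#' skipped, the rest continue.
#'
#' @param graph a `scape_graph`.
#' @param regions named list of region masks (>= 2).
#' @return object of class `current_map`: `current` ([scape_grid]), `pairs`
#'   (data.frame with per-pair effective resistance), `errors` (named list).
#' @export
cumulative_current <- function(graph, regions) {
  if (length(regions) < 2) stop("need >= 2 node regions")
  if (is.null(names(regions)))
    names(regions) <- paste0("region", seq_along(regions))
  nm <- names(regions)
  acc <- matrix(0, nrow(graph$node_id), ncol(graph$node_id))
  pairs <- NULL
  errors <- list()
  for (a in seq_len(length(regions) - 1)) {
    for (b in seq(a + 1, length(regions))) {
      res <- tryCatch(solve_pair(graph, regions[[a]], regions[[b]]),
                      error = function(e) e)
      key <- paste(nm[a], nm[b], sep = "-")
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        next
      }
      cv <- grid_values(res$current)
      cv[is.na(cv)] <- 0
      acc <- acc + cv
      pairs <- rbind(pairs, data.frame(
        pair = key, effective_resistance = res$effective_resistance))
    }
  }
  acc[is.na(graph$node_id)] <- NA_real_
  structure(list(current = grid_like(graph$grid, acc), pairs = pairs,
                 errors = errors),
            class = "current_map")
}

#' @export
print.current_map <- function(x, ...) {
  cat("<current_map>", nrow(x$pairs), "region pairs solved")
  if (length(x$errors)) cat(",", length(x$errors), "failed")
  cat("\n")
  print(x$pairs)
  invisible(x)
}

#' Equal-count quantile classification of a current map
#'
#' Bins valid cells with positive current into `n_bins` equal-count classes
#' (bin `n_bins` = highest current); zero-current and nodata cells are left
#' unclassified. This is the decile visualization used to highlight
#' corridors in otherwise low-permeability landscapes.
#'
#' @param current_map a `current_map` or current [scape_grid].
#' @param n_bins number of quantile bins (default 10).
#' @return [scape_grid] of bins 1..`n_bins` (NA elsewhere).
#' @export
quantile_classify <- function(current_map, n_bins = 10) {
  g <- if (inherits(current_map, "current_map")) current_map$current
       else current_map
  v <- grid_values(g)
  pos <- which(!is.na(v) & v > 0)
  if (length(unique(v[pos])) < n_bins)
    stop("fewer than ", n_bins, " distinct positive values; cannot bin")
  r <- rank(v[pos], ties.method = "first")
  bins <- floor((r - 1) * n_bins / length(pos)) + 1
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[pos] <- bins
  grid_like(g, out)
}
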