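# Small in-code fixtures shared across test files.

# a tiny two-class landscape with roads/streams and a scaled covariate stack
small_world <- function(nrow = 80, ncol = 80, cellsize = 30, seed = 101,
                        scales = c(0.5, 1)) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, cellsize = cellsize,
                          autocorr_range = 5)
  lc <- generate_landcover(cfg, seed = seed)
  ln <- generate_lines(cfg, seed = seed)
  stack <- build_covariates(lc, ln, scales_km2 = scales,
                            prop_classes = c("forest", "pasture"),
                            density_window_km2 = scales[1])
  list(cfg = cfg, landcover = lc, lines = ln,
       stack = scale_covariates(stack))
}

# dense Laplacian pseudoinverse effective resistance (independent oracle)
pinv_effective_resistance <- function(graph, idA, idB) {
  L <- matrix(0, graph$n, graph$n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; cc <- graph$edges$cond[r]
    L[i, j] <- L[i, j] - cc; L[j, i] <- L[j, i] - cc
    L[i, i] <- L[i, i] + cc; L[j, j] <- L[j, j] + cc
  }
  # contract the regions by summing rows/cols
  groups <- seq_len(graph$n)
  groups[idA] <- idA[1]; groups[idB] <- idB[1]
  keep <- sort(unique(groups))
  M <- matrix(0, graph$n, length(keep))
  M[cbind(seq_len(graph$n), match(groups, keep))] <- 1
  Lc <- t(M) %*% L %*% M  # contraction of a Laplacian is a Laplacian
  Lp <- MASS::ginv(Lc)
  e <- numeric(length(keep))
  e[match(idA[1], keep)] <- 1
  e[match(idB[1], keep)] <- -1
  drop(t(e) %*% Lp %*% e)
}

# random connected resistance grid graph with <= nmax nodes
random_grid_graph <- function(nmax = 200) {
  nr <- sample(3:12, 1); nc <- sample(3:12, 1)
  while (nr * nc > nmax) { nr <- sample(3:12, 1); nc <- sample(3:12, 1) }
  R <- scape_grid(matrix(stats::runif(nr * nc, 1, 100), nr, nc), 30)
  list(grid = R, graph = grid_to_graph(R), nr = nr, nc = nc)
}

corner_regions <- function(nr, nc) {
  A <- matrix(FALSE, nr, nc); A[1, 1] <- TRUE
  B <- matrix(FALSE, nr, nc); B[nr, nc] <- TRUE
  list(A = A, B = B)
}
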