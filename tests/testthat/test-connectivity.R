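test_that("resistance transforms hit their endpoints and hand values", {
  for (cc in c(2, 8)) {
    tr <- resistance_transform("exponential", cc)
    expect_equal(suitability_to_resistance(0, tr), 100)
    expect_equal(suitability_to_resistance(1, tr), 1)
  }
  lin <- resistance_transform("linear")
  expect_equal(suitability_to_resistance(c(0, 1), lin), c(100, 1))
  # hand evaluation with e^-1 = 0.367879, e^-2 = 0.135335
  expect_equal(suitability_to_resistance(0.5, resistance_transform("exponential", 2)),
               27.625, tolerance = 1e-3)
  # strictly decreasing in H
  H <- seq(0, 1, 0.01)
  for (tr2 in list(lin, resistance_transform("exponential", 2),
                   resistance_transform("exponential", 8)))
    expect_true(all(diff(suitability_to_resistance(H, tr2)) < 0))
  expect_error(resistance_transform("exponential", 0), "degenerate")
  expect_warning(suitability_to_resistance(c(-0.2, 0.5), lin), "clipped")
})

test_that("the conductance graph follows the 8-neighbor convention", {
  g <- grid_to_graph(scape_grid(matrix(2, 3, 3), 30))
  # 12 cardinal + 8 diagonal edges
  expect_equal(nrow(g$edges), 20L)
  card <- g$edges$cond[abs(g$edges$cond - 0.5) < 1e-12]
  expect_equal(length(card), 12L)
  diag_e <- g$edges$cond[abs(g$edges$cond - 0.5 / sqrt(2)) < 1e-12]
  expect_equal(length(diag_e), 8L)

  # nodata cell is excluded entirely (degree 0)
  m <- matrix(5, 3, 3); m[2, 2] <- -9999
  g2 <- grid_to_graph(scape_grid(m, 30))
  expect_equal(g2$n, 8L)
  expect_true(all(is.na(g2$node_id[2, 2])))
  expect_error(grid_to_graph(scape_grid(matrix(-9999, 2, 2), 30)),
               "all-nodata")
})

test_that("current flow matches series and parallel circuit laws", {
  # 1x3 chain with unit edge resistances: Reff = 2, middle current = 1
  ch <- grid_to_graph(scape_grid(matrix(1, 1, 3), 30), neighborhood = 4)
  s <- solve_pair(ch, matrix(c(TRUE, FALSE, FALSE), 1, 3),
                  matrix(c(FALSE, FALSE, TRUE), 1, 3))
  expect_equal(s$effective_resistance, 2, tolerance = 1e-12)
  expect_equal(grid_values(s$current)[1, 2], 1, tolerance = 1e-12)

  # two disjoint 2-resistance paths in parallel: Reff = 1
  par <- grid_to_graph(scape_grid(matrix(2, 2, 2), 30), neighborhood = 4)
  A <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  s2 <- solve_pair(par, A, !A)
  expect_equal(s2$effective_resistance, 1, tolerance = 1e-12)

  # mirror-symmetric landscape gives a mirror-symmetric current map
  set.seed(61)
  half <- matrix(runif(6 * 4, 1, 40), 6, 4)
  Rm <- cbind(half, half[, 4:1])
  g <- grid_to_graph(scape_grid(Rm, 30))
  A3 <- matrix(FALSE, 6, 8); A3[3, 1] <- TRUE
  B3 <- matrix(FALSE, 6, 8); B3[3, 8] <- TRUE
  s3 <- solve_pair(g, A3, B3)
  cur <- grid_values(s3$current)
  expect_equal(cur, cur[, 8:1], tolerance = 1e-8)
})

test_that("current is conserved at interior nodes", {
  set.seed(62)
  for (rep in 1:5) {
    rg <- random_grid_graph(150)
    regs <- corner_regions(rg$nr, rg$nc)
    s <- solve_pair(rg$graph, regs$A, regs$B)
    e <- rg$graph$edges
    icur <- e$cond * (s$potentials[e$i] - s$potentials[e$j])
    net <- rowsum(c(icur, -icur), c(e$i, e$j))
    interior <- setdiff(seq_len(rg$graph$n),
                        c(rg$graph$node_id[1, 1],
                          rg$graph$node_id[rg$nr, rg$nc]))
    expect_lt(max(abs(net[as.character(interior), 1])), 1e-8)
  }
})

test_that("effective resistance matches the dense pseudoinverse oracle", {
  set.seed(63)
  for (rep in 1:50) {
    rg <- random_grid_graph(200)
    # random single- or multi-cell regions in opposite corners
    A <- matrix(FALSE, rg$nr, rg$nc)
    B <- matrix(FALSE, rg$nr, rg$nc)
    A[1:sample(1:2, 1), 1] <- TRUE
    B[rg$nr, (rg$nc - sample(1:2, 1) + 1):rg$nc] <- TRUE
    s <- solve_pair(rg$graph, A, B)
    idA <- selscape:::region_nodes(rg$graph, A)
    idB <- selscape:::region_nodes(rg$graph, B)
    oracle <- pinv_effective_resistance(rg$graph, idA, idB)
    expect_equal(s$effective_resistance, oracle, tolerance = 1e-8)
  }
})

test_that("effective resistance obeys Rayleigh monotonicity and scaling", {
  set.seed(64)
  R0 <- matrix(runif(80, 5, 60), 8, 10)
  g0 <- grid_to_graph(scape_grid(R0, 30))
  regs <- corner_regions(8, 10)
  r0 <- solve_pair(g0, regs$A, regs$B)$effective_resistance
  for (i in 1:20) {
    Rp <- R0
    cell <- sample(80, 1)
    Rp[cell] <- Rp[cell] * runif(1, 0.2, 0.95)  # lower one cell's resistance
    rp <- solve_pair(grid_to_graph(scape_grid(Rp, 30)), regs$A,
                     regs$B)$effective_resistance
    expect_lte(rp, r0 + 1e-10)
  }
  # scaling all resistances by alpha scales Reff by alpha and leaves the
  # normalized current map unchanged
  alpha <- 3.7
  sa <- solve_pair(grid_to_graph(scape_grid(R0, 30)), regs$A, regs$B)
  sb <- solve_pair(grid_to_graph(scape_grid(alpha * R0, 30)), regs$A, regs$B)
  expect_equal(sb$effective_resistance, alpha * sa$effective_resistance,
               tolerance = 1e-10)
  ca <- grid_values(sa$current); cb <- grid_values(sb$current)
  expect_equal(cb / mean(cb), ca / mean(ca), tolerance = 1e-10)
})

test_that("disconnected regions raise a component-aware error", {
  m <- matrix(1, 3, 5); m[, 3] <- -9999  # wall of nodata
  g <- grid_to_graph(scape_grid(m, 30))
  A <- matrix(FALSE, 3, 5); A[2, 1] <- TRUE
  B <- matrix(FALSE, 3, 5); B[2, 5] <- TRUE
  expect_error(solve_pair(g, A, B), "connected components")
  expect_error(solve_pair(g, A, A), "disjoint")
})

test_that("cumulative current sums all unordered region pairs", {
  set.seed(65)
  R <- scape_grid(matrix(runif(400, 1, 50), 20, 20), 30)
  g <- grid_to_graph(R)
  mk <- function(r, c) { m <- matrix(FALSE, 20, 20); m[r, c] <- TRUE; m }
  regs2 <- list(a = mk(1:2, 1:2), b = mk(19:20, 19:20))
  cm2 <- cumulative_current(g, regs2)
  sp <- solve_pair(g, regs2$a, regs2$b)
  expect_equal(grid_values(cm2$current), grid_values(sp$current),
               tolerance = 1e-12)
  expect_equal(cm2$pairs$effective_resistance, sp$effective_resistance)

  regs5 <- list(a = mk(1:2, 1:2), b = mk(1:2, 19:20), c = mk(19:20, 1:2),
                d = mk(19:20, 19:20), e = mk(10:11, 10:11))
  cm5 <- cumulative_current(g, regs5)
  expect_equal(nrow(cm5$pairs), choose(5, 2))
  # permuting the region order leaves the map unchanged
  cm5b <- cumulative_current(g, regs5[c(3, 5, 1, 4, 2)])
  expect_equal(grid_values(cm5$current), grid_values(cm5b$current),
               tolerance = 1e-10)
})

test_that("quantile classification produces equal-count monotone deciles", {
  g <- scape_grid(matrix(1:100, 10, 10), 30)
  q <- quantile_classify(g, 10)
  v <- grid_values(q)
  expect_equal(v[g$values == 95], 10)
  expect_equal(as.vector(table(v)), rep(10L, 10))

  set.seed(66)
  for (i in 1:5) {
    gm <- scape_grid(matrix(rexp(400), 20, 20), 30)
    qq <- grid_values(quantile_classify(gm, 10))
    counts <- table(qq)
    expect_true(max(counts) - min(counts) <= 1)
    # strictly higher current never gets a lower bin
    vv <- as.vector(grid_values(gm)); bb <- as.vector(qq)
    o <- order(vv)
    expect_true(all(diff(bb[o]) >= 0 | diff(vv[o]) == 0))
  }
  expect_error(quantile_classify(scape_grid(matrix(1, 5, 5), 30), 10),
               "distinct")
})
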