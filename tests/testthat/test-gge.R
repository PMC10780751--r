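test_that("environment centering and variance accounting are exact", {
  s <- simulate_met(g = 10, e = 5, r = 2, seed = 61)
  g1 <- fit_gge(s$data)
  expect_lt(max(abs(colSums(g1$centered))), 1e-9)
  expect_equal(sum(g1$pct_explained), 100, tolerance = 1e-9)

  # no genotype effect, no GEI (constant columns) -> centered matrix zero
  v <- matrix(rep(c(0, 10, -3), each = 5), 5)
  g0 <- fit_gge(new_ge_matrix(v))
  expect_equal(max(abs(g0$centered)), 0)
  expect_equal(max(abs(g0$gen_coords)), 0)
})

test_that("sd scaling rejects zero-variance environments by name", {
  v <- cbind(E1 = c(1, 2, 3), E2 = c(5, 5, 5), E3 = c(2, 4, 8))
  rownames(v) <- paste0("G", 1:3)
  expect_error(fit_gge(new_ge_matrix(v), scaling = "sd"), "E2")
})

test_that("rank-2 structure is reconstructed exactly and is Eckart-Young optimal", {
  set.seed(71)
  # build an exactly rank-2 environment-centered matrix
  u <- qr.Q(qr(scale(matrix(rnorm(8 * 2), 8), center = TRUE, scale = FALSE)))[, 1:2]
  w <- qr.Q(qr(matrix(rnorm(5 * 2), 5)))[, 1:2]
  centered <- u %*% diag(c(9, 4)) %*% t(w)
  v <- sweep(centered, 2, rnorm(5, 100, 5), `+`)
  g2 <- fit_gge(new_ge_matrix(v))
  recon <- g2$gen_coords %*% t(g2$env_coords)
  expect_equal(recon, g2$centered, tolerance = 1e-9, ignore_attr = TRUE)

  # a generic matrix: the rank-2 SVD truncation beats random rank-2 fits
  v3 <- matrix(rnorm(40, 50, 10), 8, 5)
  g3 <- fit_gge(new_ge_matrix(v3))
  err_svd <- sum((g3$centered - g3$gen_coords %*% t(g3$env_coords))^2)
  for (i in 1:50) {
    a <- matrix(rnorm(16), 8, 2); b <- matrix(rnorm(10), 5, 2)
    ab <- a %*% t(b)
    scale_opt <- sum(g3$centered * ab) / sum(ab^2)  # best scalar multiple
    expect_gte(sum((g3$centered - scale_opt * ab)^2), err_svd - 1e-9)
  }
})

test_that("SVP modes repartition the singular values without changing inner products", {
  s <- simulate_met(g = 9, e = 5, r = 2, seed = 73)
  m <- cell_means(s$data)
  modes <- c("symmetric", "genotype", "environment")
  recons <- lapply(modes, function(sv) {
    g <- fit_gge(m, svp = sv)
    g$gen_coords %*% t(g$env_coords)
  })
  expect_equal(recons[[1]], recons[[2]], tolerance = 1e-9)
  expect_equal(recons[[1]], recons[[3]], tolerance = 1e-9)
})

test_that("which-won-where assigns environments to the vertex with maximal dot product", {
  gc <- rbind(c(2, 0), c(0, 2), c(-1, -1))
  ec <- rbind(c(1, 0.1), c(0.1, 1))
  model <- gge_from_coords(gc, ec)
  www <- which_won_where(model)
  expect_equal(www$sectors$winner, c("G1", "G2"))
  expect_true(all(www$sectors$winner %in% www$hull_vertices))

  # a dominant genotype wins every sector
  gcd <- rbind(c(10, 0), c(0.5, 0.4), c(-0.5, 0.2), c(0, -0.6))
  ecd <- rbind(c(2, 0.1), c(1, -0.2), c(3, 0.05))
  wd <- which_won_where(gge_from_coords(gcd, ecd))
  expect_true(all(wd$sectors$winner == "G1"))

  # collinear genotype points are degenerate
  gcl <- cbind(1:4, 2 * (1:4))
  expect_error(which_won_where(gge_from_coords(gcl, ecd)),
               "degenerate")
})

test_that("sector winners equal the rank-2 model argmax on random matrices", {
  set.seed(83)
  for (i in 1:40) {
    v <- matrix(rnorm(24, 100, 10), 6, 4)
    model <- fit_gge(new_ge_matrix(v), svp = "symmetric")
    www <- which_won_where(model)
    rank2 <- model$gen_coords %*% t(model$env_coords)
    oracle_winner <- rownames(model$gen_coords)[apply(rank2, 2, which.max)]
    expect_equal(www$sectors$winner, oracle_winner)
  }
})

test_that("hull vertices match the brute-force convex-combination test", {
  set.seed(89)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    model <- gge_from_coords(pts, rbind(c(1, 0), c(0, 1)))
    www <- which_won_where(model)
    oracle <- sort(paste0("G", hull_vertices_bruteforce(pts)))
    expect_equal(sort(www$hull_vertices), oracle)
  }
})

test_that("winners, sectors and rankings are rotation and sign invariant", {
  s <- simulate_met(g = 12, e = 6, r = 2, seed = 97)
  model <- fit_gge(s$data, svp = "symmetric")
  www0 <- which_won_where(model)
  ms0 <- mean_vs_stability(model)
  set.seed(5)
  for (i in 1:5) {
    theta <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    flip <- diag(sample(c(-1, 1), 2, replace = TRUE))
    tf <- rot %*% flip
    m2 <- model
    m2$gen_coords <- model$gen_coords %*% tf
    m2$env_coords <- model$env_coords %*% tf
    www2 <- which_won_where(m2)
    expect_equal(www2$sectors$winner, www0$sectors$winner)
    expect_equal(sort(www2$hull_vertices), sort(www0$hull_vertices))
    ms2 <- mean_vs_stability(m2)
    expect_equal(ms2$rank, ms0$rank)
    expect_equal(ms2$mean_proj, ms0$mean_proj, tolerance = 1e-9)
    expect_equal(abs(ms2$stab_dist), abs(ms0$stab_dist), tolerance = 1e-9)
  }
})

test_that("mean-vs-stability projects onto the average environment axis", {
  # constructed coordinates: AEA along +x
  gc <- rbind(c(3, 0), c(3, 2), c(1, 0), c(-2, 1))
  ec <- rbind(c(1, 0.2), c(1, -0.2), c(2, 0))
  ms <- mean_vs_stability(gge_from_coords(gc, ec))
  expect_equal(attr(ms, "aea_direction"), c(1, 0), tolerance = 1e-12)
  expect_equal(ms$mean_proj, c(3, 3, 1, -2))
  expect_equal(ms$stab_dist, c(0, 2, 0, 1))
  # G1 attains the max projection on the AEA itself -> ideal, rank 1
  expect_equal(ms$dist_to_ideal[1], 0)
  expect_equal(ms$rank[1], 1)
  # equal projections: smaller |stab_dist| ranks better (G1 vs G2)
  expect_lt(ms$rank[1], ms$rank[2])

  # degenerate: average environment at the origin
  ec0 <- rbind(c(1, 0), c(-1, 0))
  expect_error(mean_vs_stability(gge_from_coords(gc, ec0)), "undefined AEA")
})

test_that("without interaction the AEA ordering is the mean-yield ordering", {
  s <- simulate_met(g = 8, e = 5, r = 2, ss_fractions = c(0.6, 0.4, 0),
                    noise_sd = 0, block_sd = 0, seed = 7)
  model <- fit_gge(s$data, svp = "genotype")
  ms <- mean_vs_stability(model)
  m <- cell_means(s$data)
  expect_equal(order(ms$mean_proj), order(m$gen_means[ms$gen]))
})
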