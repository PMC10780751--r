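# Hand-worked 3 genotype x 3 environment means matrix used across the suite.
# Rows (10,20,30), (20,25,30), (30,30,30):
#   env means (20, 25, 30), gen means (20, 25, 30), grand 25
#   double-centered: (-5,0,5), (0,0,0), (5,0,-5)  -- rank 1, lambda = 10
#   ecovalence (50, 0, 50); Shukla (50, -25, 50); ER slopes (2, 1, 0);
#   S2d (0,0,0); Pi_a (500/6, 125/6, 0); GAI_1 = 6000^(1/3);
#   raw within-env ranks (1,1,2), (2,2,2), (3,3,2) -> Huehn S1 (2/3, 0, 2/3)
hand_matrix <- function() {
  new_ge_matrix(matrix(c(10, 20, 30,
                         20, 25, 30,
                         30, 30, 30),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(paste0("G", 1:3), paste0("E", 1:3))),
                r = 1L)
}

# long plot-level data from a means matrix, r identical replicates
met_from_matrix <- function(m, r = 2) {
  v <- if (inherits(m, "ge_matrix")) m$values else m
  grid <- expand.grid(rep = paste0("R", seq_len(r)),
                      env = colnames(v), gen = rownames(v),
                      stringsAsFactors = FALSE)
  grid$yield <- v[cbind(grid$gen, grid$env)]
  tibble::as_tibble(grid[c("env", "gen", "rep", "yield")])
}

# purely additive dataset: mu + alpha_g + beta_e, r identical reps
additive_met <- function(alpha = c(-10, 0, 10, 25), beta = c(-20, 5, 15),
                         mu = 100, r = 2) {
  v <- mu + outer(alpha, beta, `+`)
  dimnames(v) <- list(paste0("G", seq_along(alpha)),
                      paste0("E", seq_along(beta)))
  met_from_matrix(v, r = r)
}

# independent oracle: leading singular value by power iteration + deflation
power_iteration_svals <- function(m, k = min(dim(m)), iters = 5000) {
  m <- as.matrix(m)
  out <- numeric(k)
  for (i in seq_len(k)) {
    v <- rep(1 / sqrt(ncol(m)), ncol(m)) + seq_len(ncol(m)) * 1e-3
    v <- v / sqrt(sum(v^2))
    for (it in seq_len(iters)) {
      w <- crossprod(m, m %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      v <- w / nw
    }
    s <- sqrt(sum((m %*% v)^2))
    out[i] <- s
    if (s > 0) {
      u <- (m %*% v) / s
      m <- m - s * tcrossprod(u, v)
    }
  }
  out
}

# independent oracle: is point p inside the convex hull of rows of pts?
# (2-D Caratheodory: inside iff contained in some triangle of three points)
in_hull_bruteforce <- function(p, pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  combos <- utils::combn(n, 3)
  for (j in seq_len(ncol(combos))) {
    a <- pts[combos[1, j], ]; b <- pts[combos[2, j], ]; c <- pts[combos[3, j], ]
    den <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(den) < 1e-12) next
    l1 <- ((b[2] - c[2]) * (p[1] - c[1]) + (c[1] - b[1]) * (p[2] - c[2])) / den
    l2 <- ((c[2] - a[2]) * (p[1] - c[1]) + (a[1] - c[1]) * (p[2] - c[2])) / den
    l3 <- 1 - l1 - l2
    if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) return(TRUE)
  }
  FALSE
}

# brute-force hull vertex set: points NOT inside the hull of the others
hull_vertices_bruteforce <- function(pts) {
  which(!vapply(seq_len(nrow(pts)), function(i) {
    in_hull_bruteforce(pts[i, ], pts[-i, , drop = FALSE])
  }, logical(1)))
}

# do two cluster label vectors describe the same partition?
same_partition <- function(a, b) {
  ta <- outer(a, a, `==`)
  tb <- outer(b, b, `==`)
  all(ta == tb)
}

# a means matrix with a nonpositive cell (GAI error path)
hand_matrix_nonpos <- function() {
  new_ge_matrix(matrix(c(-1, 2, 3, 4, 5, 6, 7, 8, 9), 3))
}

# minimal gge_model built from explicit 2-D coordinates (geometry tests)
gge_from_coords <- function(gen_coords, env_coords) {
  rownames(gen_coords) <- paste0("G", seq_len(nrow(gen_coords)))
  rownames(env_coords) <- paste0("E", seq_len(nrow(env_coords)))
  structure(list(gen_coords = gen_coords, env_coords = env_coords,
                 pct_explained = c(60, 40), svp = "symmetric",
                 scaling = "none"),
            class = "gge_model")
}
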