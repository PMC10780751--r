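test_that("hand 3x3 matrix reproduces the full worked stability panel", {
  m <- hand_matrix()
  st <- parametric_stability(m)
  expect_equal(st$ecoval, c(50, 0, 50))
  expect_equal(sum(st$ecoval), sum(double_center(m)^2))
  expect_equal(st$shukla, c(50, -25, 50))
  expect_equal(st$er_slope, c(2, 1, 0))
  expect_equal(mean(st$er_slope), 1)
  expect_equal(st$er_s2d, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(st$pi_a, c(500 / 6, 125 / 6, 0))
  expect_equal(st$gai[1], 6000^(1 / 3), tolerance = 1e-12)
  # constant genotype row: no env variance, no CV, GAI = the constant
  expect_equal(st$s2_xi[3], 0)
  expect_equal(st$cv[3], 0)
  expect_equal(st$gai[3], 30)

  np <- nonparametric_stability(m)
  expect_equal(np$s1, c(2 / 3, 0, 2 / 3))

  w <- waas(fit_ammi(m), n_axes = "all")
  expect_equal(w$waas, c(sqrt(5), 0, sqrt(5)), tolerance = 1e-9)
})

test_that("Shukla variances are the documented linear transform of ecovalence", {
  s <- simulate_met(g = 12, e = 5, r = 2, seed = 19)
  m <- cell_means(s$data)
  st <- parametric_stability(m)
  g <- 12; e <- 5
  ss_gei <- sum(double_center(m)^2)
  expect_equal(st$shukla,
               g * st$ecoval / ((g - 2) * (e - 1)) -
                 ss_gei / ((g - 1) * (g - 2) * (e - 1)),
               tolerance = 1e-12)
  expect_equal(sum(st$shukla), g * ss_gei / ((g - 1) * (e - 1)),
               tolerance = 1e-9)
  st_r <- rank_table(st)
  expect_equal(st_r$Shukla_R, st_r$Ecoval_R)
})

test_that("purely additive data are maximally stable on every index", {
  d <- additive_met(alpha = c(-20, -5, 5, 20), beta = c(-30, 0, 30), mu = 200)
  m <- cell_means(d)
  st <- parametric_stability(m)
  expect_equal(st$ecoval, rep(0, 4), tolerance = 1e-18)
  expect_equal(st$er_slope, rep(1, 4), tolerance = 1e-12)
  expect_equal(st$er_s2d, rep(0, 4), tolerance = 1e-18)
  st_r <- rank_table(st)
  expect_equal(st_r$Pi_a_R, st_r$Y_R)  # Pi ranks collapse to mean-yield ranks
  np <- nonparametric_stability(m)
  # same within-env rank everywhere -> zero rank dispersion
  expect_equal(np$s1, rep(0, 4))
  expect_equal(np$s2, rep(0, 4))
  expect_equal(np$n1, rep(0, 4))
  # corrected ranks remove the genotype effect entirely
  expect_equal(np$s3, np$s3[1] + rep(0, 4))
  expect_equal(np$s6, np$s6[1] + rep(0, 4))
})

test_that("AM-GM: GAI never exceeds the arithmetic mean", {
  s <- simulate_met(g = 10, e = 6, r = 2, seed = 29)
  st <- parametric_stability(cell_means(s$data))
  expect_true(all(st$gai <= st$mean_yield + 1e-9))
  m <- new_ge_matrix(matrix(30, 3, 3))
  stc <- suppressWarnings(parametric_stability(m))
  expect_equal(stc$gai, stc$mean_yield)
  expect_error(parametric_stability(hand_matrix_nonpos()),
               "nonpositive", fixed = TRUE)
})

test_that("Annicchiarico and Lin-Binns split by environment favorability", {
  m <- hand_matrix()  # env means 20, 25, 30; grand 25 -> only E3 favorable
  st <- parametric_stability(m)
  # favorable subset = E3 only: percentages 100*x/30, single env -> sd NA
  expect_true(all(is.na(st$wi_f)))
  expect_equal(st$pi_f, (c(30, 30, 30) - m$values[, 3])^2 / 2,
               ignore_attr = TRUE)
  expect_equal(st$pi_u,
               ((m$values[, 1] - 30)^2 + (m$values[, 2] - 30)^2) / 4,
               ignore_attr = TRUE)
  # all environments identical -> favorable subset empty, columns NA
  flat <- new_ge_matrix(matrix(rep(c(1, 2, 3), 3), 3))
  expect_warning(st2 <- parametric_stability(flat), "subset empty")
  expect_true(all(is.na(st2$wi_f)) && all(is.na(st2$pi_f)))
})

test_that("Tai's alpha is the joint-regression excess slope in disguise", {
  s <- simulate_met(g = 10, e = 6, r = 3, seed = 43)
  m <- cell_means(s$data)
  a <- met_anova(s$data)
  st <- parametric_stability(m, anova = a)
  # alpha_i = (b_i - 1) * Sum I^2 / S3 -> perfectly collinear with b_i - 1
  expect_gt(cor(st$tai_alpha, st$er_slope - 1), 0.999999)
  expect_true(all(is.finite(st$tai_lambda)) && all(st$tai_lambda >= 0))
  # without replicate-level error information the columns are NA
  st0 <- parametric_stability(m)
  expect_true(all(is.na(st0$tai_alpha)))
})

test_that("WAAS collapses to |IPCA1| with one axis and is zero for null scores", {
  m <- fit_ammi(hand_matrix())
  w1 <- waas(m, n_axes = 1)
  expect_equal(w1$waas, abs(m$gen_scores[, 1]), ignore_attr = TRUE)
  expect_equal(w1$waas[2], 0)
  expect_error(waas(m), "none significant")
  s <- simulate_met(g = 8, e = 5, r = 2, seed = 3)
  mod <- fit_ammi(s$data)
  w <- waas(mod, n_axes = "all")
  manual <- as.vector(abs(mod$gen_scores) %*% mod$axes$prop / sum(mod$axes$prop))
  expect_equal(w$waas, manual)
})

test_that("yield-WAAS quadrants follow the documented boundary rules", {
  q <- gy_waas_quadrants(means = c(10, 12), waas = c(3, 1),
                         labels = c("low_unstable", "high_stable"))
  expect_equal(as.character(q$quadrant), c("I", "IV"))
  # all points identical -> everything on the boundary -> quadrant I
  q2 <- gy_waas_quadrants(rep(5, 4), rep(2, 4))
  expect_true(all(q2$quadrant == "I"))
  # high-yield zero-interaction genotype lands in quadrant IV
  v <- hand_matrix()$values
  v[2, ] <- v[2, ] + 40  # G2: zero interaction, now highest mean
  d <- met_from_matrix(v, r = 2)
  st <- stability_table(d, n_axes = "all")
  q3 <- gy_waas_quadrants(st$mean_yield, st$waas, st$gen)
  expect_equal(as.character(q3$quadrant[q3$label == "G2"]), "IV")
})

test_that("rank directions: ascending indices, |b-1|, descending yield and GAI", {
  st <- tibble::tibble(gen = paste0("G", 1:3),
                       ecoval = c(50, 0, 50),
                       mean_yield = c(5, 7, 6),
                       er_slope = c(2, 1, 0),
                       gai = c(1, 3, 2),
                       s1 = c(0.1, 0.2, 0.3))
  rt <- rank_table(st)
  expect_equal(rt$Ecoval_R, c(2.5, 1, 2.5))
  expect_equal(rt$Y_R, c(3, 1, 2))
  expect_equal(rt$Gai_R, c(3, 1, 2))
  expect_equal(rt$bi_R, c(2.5, 1, 2.5))
  expect_equal(rt$S1_R, 1:3, ignore_attr = TRUE)
  neg <- rank_table(dplyr::mutate(st, s1 = -s1))
  expect_equal(neg$S1_R, 3:1, ignore_attr = TRUE)
})

test_that("stability_table assembles values, ranks and passes invariants", {
  s <- simulate_met(g = 10, e = 6, r = 3, seed = 51)
  st <- stability_table(s$data)
  expect_equal(nrow(st), 10)
  rank_cols <- grep("_R$", names(st), value = TRUE)
  expect_true(all(c("Shukla_R", "Wi_g_R", "Wi_f_R", "Wi_u_R", "Ecoval_R",
                    "Sij_R", "Pi_a_R", "Pi_f_R", "Pi_u_R", "Gai_R",
                    "S1_R", "S2_R", "S3_R", "S6_R", "N1_R") %in% rank_cols))
  for (col in rank_cols) {
    r <- st[[col]]
    if (all(is.na(r))) next
    expect_equal(sum(r), sum(seq_len(10)), info = col)  # tie-averaged permutation
  }
  # ecovalence sums to the means-level interaction SS
  m <- cell_means(s$data)
  expect_equal(sum(st$ecoval), sum(double_center(m)^2), tolerance = 1e-9)
})

test_that("rank statistics ignore environment relabeling", {
  s <- simulate_met(g = 8, e = 5, r = 2, seed = 57)
  m <- cell_means(s$data)
  np1 <- nonparametric_stability(m)
  perm <- m$values[, c(3, 1, 5, 2, 4)]
  np2 <- nonparametric_stability(new_ge_matrix(perm))
  expect_equal(np1[-1], np2[-1])
})
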