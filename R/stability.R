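#' Weighted average of absolute scores (WAAS)
#'
#' For each genotype, the weighted average of the absolute values of its
#' interaction principal component scores, weighted by the percent of GEI
#' each axis explains:
#' \deqn{WAAS_i = \sum_k |s_{ik}| EP_k / \sum_k EP_k.}
#' Small WAAS = stable genotype.
#'
#' @param model An `ammi_model`.
#' @param n_axes `"significant"` (axes passing the Gollob F-test at the
#'   model's `sig_level`; default), `"all"`, or an integer number of leading
#'   axes.
#' @param role `"genotype"` (default) or `"environment"` — whose scores to
#'   average.
#' @return Tibble with `gen` (or `env`) and `waas`.
#' @export
waas <- function(model, n_axes = "significant", role = c("genotype", "environment")) {
  stopifnot(inherits(model, "ammi_model"))
  role <- match.arg(role)
  p <- nrow(model$axes)
  sel <- if (identical(n_axes, "significant")) {
    which(model$axes$significant)
  } else if (identical(n_axes, "all")) {
    seq_len(p)
  } else {
    stopifnot(is.numeric(n_axes), n_axes >= 1, n_axes <= p)
    seq_len(as.integer(n_axes))
  }
  if (length(sel) == 0) {
    stop("no interaction axes available for WAAS (none significant; ",
         "pass n_axes = 'all' or an axis count)", call. = FALSE)
  }
  scores <- if (role == "genotype") model$gen_scores else model$env_scores
  ep <- model$axes$prop[sel]
  if (sum(ep) == 0) ep <- rep(1, length(sel))  # zero-GEI degenerate case
  w <- abs(scores[, sel, drop = FALSE]) %*% ep / sum(ep)
  out <- tibble::tibble(label = rownames(scores), waas = as.vector(w))
  names(out)[1] <- if (role == "genotype") "gen" else "env"
  out
}

#' Quadrants of the yield-versus-WAAS biplot
#'
#' Splits points at the mean yield (vertical line) and mean WAAS (horizontal
#' line): quadrant I = below-mean yield, above-mean WAAS (low yielding,
#' unstable); II = above-mean yield, above-mean WAAS; III = below-mean yield,
#' below-mean WAAS (low yielding but stable); IV = above-mean yield,
#' below-mean WAAS (high yielding and stable — the broadly adapted set).
#' Points exactly on a dividing line go to the lower-yield / higher-WAAS
#' side.
#'
#' @param means Numeric vector of mean yields.
#' @param waas Numeric vector of WAAS values, aligned with `means`.
#' @param labels Optional point labels.
#' @return Tibble with `label`, `mean_yield`, `waas`, `quadrant`
#'   (factor I-IV).
#' @export
gy_waas_quadrants <- function(means, waas, labels = names(means)) {
  stopifnot(length(means) == length(waas))
  if (is.null(labels)) labels <- as.character(seq_along(means))
  cx <- mean(means)
  cy <- mean(waas)
  high_gy <- means > cx        # equality -> lower-GY side
  high_waas <- waas >= cy      # equality -> higher-WAAS side
  q <- dplyr::case_when(
    !high_gy & high_waas ~ "I",
    high_gy & high_waas ~ "II",
    !high_gy & !high_waas ~ "III",
    TRUE ~ "IV")
  tibble::tibble(label = labels, mean_yield = unname(means),
                 waas = unname(waas),
                 quadrant = factor(q, levels = c("I", "II", "III", "IV")))
}

#' Parametric stability statistics
#'
#' Per-genotype panel computed from the cell-means matrix:
#' * Wricke ecovalence `W_i`: summed squared interaction residuals.
#' * Shukla stability variance `sigma2_i`: unbiased variance estimate, a
#'   linear transform of `W_i`.
#' * Eberhart-Russell joint regression: slope `b_i` of genotype means on the
#'   environmental index and deviation mean square `S2d_i`.
#' * Annicchiarico reliability `Wi`: mean percent-of-environment-mean minus
#'   a one-sided normal quantile times its standard deviation, over all /
#'   favorable / unfavorable environments.
#' * Lin-Binns superiority `Pi`: mean squared distance to the per-environment
#'   maximum (halved), over all / favorable / unfavorable environments.
#' * Environmental variance `S2_xi`, coefficient of variation `CV_i`,
#'   geometric adaptability index `GAI_i`.
#' * Tai statistics `alpha_i` (linear environmental response of the
#'   interaction) and `lambda_i` (scaled deviation), when replicate-level
#'   error mean squares are supplied.
#'
#' @param m A `ge_matrix`.
#' @param cls Environment classification from [classify_environments()];
#'   computed from `m` by default.
#' @param anova Optional `met_anova` table from the same data; required for
#'   Tai's statistics (`NA` otherwise).
#' @param conf_z One-sided normal quantile for the Annicchiarico index;
#'   default `qnorm(0.75)` (75% reliability).
#' @return Tibble with one row per genotype and the columns above.
#' @export
parametric_stability <- function(m, cls = classify_environments(m),
                                 anova = NULL, conf_z = stats::qnorm(0.75)) {
  stopifnot(inherits(m, "ge_matrix"))
  x <- m$values
  g <- nrow(x); e <- ncol(x)
  if (g < 3) stop("parametric stability needs g >= 3 genotypes", call. = FALSE)
  dc <- double_center(m)
  ecoval <- rowSums(dc^2)
  ss_gei <- sum(dc^2)
  shukla <- g * ecoval / ((g - 2) * (e - 1)) -
    ss_gei / ((g - 1) * (g - 2) * (e - 1))

  ienv <- m$env_means - m$grand_mean
  s_ii <- sum(ienv^2)
  er_slope <- if (s_ii > 0) as.vector(x %*% ienv) / s_ii else rep(NA_real_, g)
  if (e >= 3 && s_ii > 0) {
    fitted <- m$gen_means + outer(er_slope, ienv)
    er_s2d <- rowSums((x - fitted)^2) / (e - 2)
  } else {
    er_s2d <- rep(NA_real_, g)
  }

  pct <- sweep(x, 2, m$env_means, `/`) * 100
  anni <- function(cols) {
    if (length(cols) == 0) return(rep(NA_real_, g))
    sub <- pct[, cols, drop = FALSE]
    apply(sub, 1, mean) - conf_z * apply(sub, 1, stats::sd)
  }
  linbinns <- function(cols) {
    if (length(cols) == 0) return(rep(NA_real_, g))
    sub <- x[, cols, drop = FALSE]
    mx <- apply(sub, 2, max)
    rowSums(sweep(sub, 2, mx)^2) / (2 * length(cols))
  }
  fav <- which(cls$class[match(colnames(x), cls$env)] == "favorable")
  unf <- setdiff(seq_len(e), fav)
  if (length(fav) == 0 || length(unf) == 0) {
    warning("favorable/unfavorable environment subset empty; ",
            "subset statistics set to NA")
  }

  s2_xi <- apply(x, 1, stats::var)
  cv <- 100 * apply(x, 1, stats::sd) / m$gen_means
  if (any(x <= 0)) {
    stop("geometric adaptability index undefined: nonpositive cell means",
         call. = FALSE)
  }
  gai <- exp(rowMeans(log(x)))

  if (!is.null(anova)) {
    r <- attr(anova, "dims")$r
    ms_rep <- anova$ms[anova$source == "REP(ENV)"]
    ms_res <- anova$ms[anova$source == "Residuals"]
    s1 <- as.vector(dc %*% ienv)
    s3 <- s_ii - (e - 1) * ms_rep / (r * g)
    tai_alpha <- s1 / s3
    if (e >= 3) {
      tai_lambda <- (rowSums(dc^2) - tai_alpha * s1) / ((e - 2) * ms_res / r)
    } else {
      tai_lambda <- rep(NA_real_, g)
    }
  } else {
    tai_alpha <- rep(NA_real_, g)
    tai_lambda <- rep(NA_real_, g)
  }

  tibble::tibble(
    gen = rownames(x),
    mean_yield = unname(m$gen_means),
    ecoval = unname(ecoval),
    shukla = unname(shukla),
    er_slope = unname(er_slope),
    er_s2d = unname(er_s2d),
    wi_g = unname(anni(seq_len(e))),
    wi_f = unname(anni(fav)),
    wi_u = unname(anni(unf)),
    pi_a = unname(linbinns(seq_len(e))),
    pi_f = unname(linbinns(fav)),
    pi_u = unname(linbinns(unf)),
    s2_xi = unname(s2_xi),
    cv = unname(cv),
    gai = unname(gai),
    tai_alpha = unname(tai_alpha),
    tai_lambda = unname(tai_lambda))
}

#' Nonparametric (rank-based) stability statistics
#'
#' Genotypes are ranked within each environment (rank 1 = lowest value,
#' average ranks on ties). Huehn's statistics:
#' * `S1`: mean absolute pairwise rank difference across environment pairs;
#' * `S2`: variance of the ranks;
#' * `S3`, `S6`: sum of squared / absolute rank deviations scaled by the mean
#'   rank, computed on ranks of genotype-effect-corrected values
#'   `x_ie - gen_mean_i + grand_mean` (so a purely additive genotype effect
#'   contributes nothing);
#' and Thennarasu's `N1`: mean absolute deviation from the genotype's median
#' rank, on uncorrected ranks.
#'
#' @param m A `ge_matrix`.
#' @return Tibble with `gen`, `s1`, `s2`, `s3`, `s6`, `n1`.
#' @export
nonparametric_stability <- function(m) {
  stopifnot(inherits(m, "ge_matrix"))
  x <- m$values
  g <- nrow(x); e <- ncol(x)
  rk <- apply(x, 2, avg_rank)                       # raw ranks
  corrected <- x - m$gen_means + m$grand_mean
  rk_c <- apply(corrected, 2, avg_rank)             # corrected ranks
  s1 <- apply(rk, 1, function(r) {
    if (e < 2) return(NA_real_)
    d <- abs(outer(r, r, `-`))
    sum(d[upper.tri(d)]) / (e * (e - 1) / 2)
  })
  s2 <- apply(rk, 1, stats::var)
  rbar_c <- rowMeans(rk_c)
  s3 <- rowSums((rk_c - rbar_c)^2) / rbar_c
  s6 <- rowSums(abs(rk_c - rbar_c)) / rbar_c
  med <- apply(rk, 1, stats::median)
  n1 <- rowMeans(abs(rk - med))
  tibble::tibble(gen = rownames(x),
                 s1 = unname(s1), s2 = unname(s2),
                 s3 = unname(s3), s6 = unname(s6), n1 = unname(n1))
}

# value column -> (rank column name, ranking rule)
# asc: smaller = better; desc: larger = better; abs1: |value - 1| ascending;
# abs0: |value| ascending
rank_spec <- function() {
  tibble::tibble(
    column = c("mean_yield", "waas", "ecoval", "shukla", "er_slope", "er_s2d",
               "wi_g", "wi_f", "wi_u", "pi_a", "pi_f", "pi_u",
               "s2_xi", "cv", "gai", "tai_alpha", "tai_lambda",
               "s1", "s2", "s3", "s6", "n1"),
    rank_name = c("Y_R", "WAAS_R", "Ecoval_R", "Shukla_R", "bi_R", "Sij_R",
                  "Wi_g_R", "Wi_f_R", "Wi_u_R", "Pi_a_R", "Pi_f_R", "Pi_u_R",
                  "S2xi_R", "CV_R", "Gai_R", "TaiA_R", "TaiL_R",
                  "S1_R", "S2_R", "S3_R", "S6_R", "N1_R"),
    rule = c("desc", "asc", "asc", "asc", "abs1", "asc",
             "desc", "desc", "desc", "asc", "asc", "asc",
             "asc", "asc", "desc", "abs0", "asc",
             "asc", "asc", "asc", "asc", "asc"))
}

#' Rank genotypes on every stability statistic
#'
#' Appends a `_R` rank column for each recognized statistic (average ranks on
#' ties, rank 1 = most desirable): stability indices are ranked ascending
#' (small = stable); mean yield, the geometric adaptability index and the
#' Annicchiarico reliability index descending (large = good); the
#' Eberhart-Russell slope by `|b - 1|` and Tai's alpha by `|alpha|`.
#'
#' @param stats Tibble of per-genotype statistics (see [stability_table()]).
#' @return `stats` with rank columns appended; all-`NA` statistics get `NA`
#'   ranks.
#' @export
rank_table <- function(stats) {
  spec <- rank_spec()
  for (i in seq_len(nrow(spec))) {
    col <- spec$column[i]
    if (!col %in% names(stats)) next
    v <- stats[[col]]
    key <- switch(spec$rule[i],
                  asc = v, desc = -v, abs1 = abs(v - 1), abs0 = abs(v))
    stats[[spec$rank_name[i]]] <-
      if (all(is.na(key))) rep(NA_real_, length(key)) else avg_rank(key)
  }
  stats
}

#' Full per-genotype stability table
#'
#' Runs the whole stability panel on a balanced MET: WAAS from the AMMI fit,
#' all parametric and nonparametric statistics, and their genotype ranks.
#'
#' @param data Plot-level MET tibble (`r >= 2` for F-tests and Tai
#'   statistics).
#' @param trait Response column; default `"yield"`.
#' @param n_axes Axes used for WAAS (see [waas()]).
#' @param conf_z Annicchiarico reliability quantile (see
#'   [parametric_stability()]).
#' @return Tibble with one row per genotype: values and `_R` rank columns.
#' @export
stability_table <- function(data, trait = "yield", n_axes = "significant",
                            conf_z = stats::qnorm(0.75)) {
  m <- cell_means(data, trait)
  anova_tab <- met_anova(data, trait)
  model <- fit_ammi(data, trait)
  w <- waas(model, n_axes = n_axes)
  par_tab <- parametric_stability(m, anova = anova_tab, conf_z = conf_z)
  np_tab <- nonparametric_stability(m)
  out <- dplyr::left_join(par_tab, w, by = "gen")
  out <- dplyr::left_join(out, np_tab, by = "gen")
  out <- dplyr::relocate(out, "waas", .after = "mean_yield")
  rank_table(out)
}

#' Plot the yield-versus-WAAS quadrant view
#'
#' @param data Plot-level MET tibble.
#' @param trait Response column.
#' @param ... Passed to [stability_table()].
#' @return A ggplot object with genotypes placed by mean yield and WAAS,
#'   colored by quadrant.
#' @export
plot_gy_waas <- function(data, trait = "yield", ...) {
  st <- stability_table(data, trait, ...)
  q <- gy_waas_quadrants(st$mean_yield, st$waas, st$gen)
  ggplot2::ggplot(q, ggplot2::aes(.data$mean_yield, .data$waas,
                                  colour = .data$quadrant,
                                  label = .data$label)) +
    ggplot2::geom_vline(xintercept = mean(q$mean_yield), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = mean(q$waas), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Mean yield (g m⁻²)", y = "WAAS") +
    ggplot2::theme_minimal()
}
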