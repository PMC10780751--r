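#' Joint analysis of variance for a balanced RCBD MET
#'
#' Partitions plot-level yield into environment, replicate-within-environment,
#' genotype, genotype-by-environment and residual strata. Environments are
#' tested against the replicate-within-environment mean square; genotypes and
#' the interaction against the pooled residual.
#'
#' @param data Plot-level MET tibble (`env`, `gen`, `rep`, `yield`),
#'   balanced, with at least 2 replicates.
#' @param trait Response column; default `"yield"`.
#' @return A `met_anova` tibble with columns `source` (`ENV`, `REP(ENV)`,
#'   `GEN`, `GEN:ENV`, `Residuals`), `df`, `ss`, `ms`, `f`, `p`.
#' @export
met_anova <- function(data, trait = "yield") {
  assert_balanced(data)
  d <- met_dims(data)
  if (d$r < 2) {
    stop("joint ANOVA needs r >= 2 replicates (no residual stratum otherwise)",
         call. = FALSE)
  }
  df <- data.frame(env = factor(data$env), gen = factor(data$gen),
                   rep = factor(data$rep), y = data[[trait]])
  fit <- stats::aov(y ~ env + gen + env:rep + env:gen, data = df)
  s <- summary(fit)[[1]]
  key <- trimws(rownames(s))
  pick <- function(term) which(key == term)
  ss <- stats::setNames(s[["Sum Sq"]], key)
  dfv <- stats::setNames(s[["Df"]], key)
  out <- tibble::tibble(
    source = c("ENV", "REP(ENV)", "GEN", "GEN:ENV", "Residuals"),
    df = as.integer(dfv[c("env", "env:rep", "gen", "env:gen", "Residuals")]),
    ss = as.numeric(ss[c("env", "env:rep", "gen", "env:gen", "Residuals")]))
  out$ms <- out$ss / out$df
  ms_rep <- out$ms[out$source == "REP(ENV)"]
  ms_res <- out$ms[out$source == "Residuals"]
  # a denominator MS that is zero to machine precision gives F = +Inf, p = 0
  safe_f <- function(num, den) {
    if (den <= num * 1e-12) {
      if (num <= 0) NaN else Inf
    } else num / den
  }
  out$f <- c(safe_f(out$ms[1], ms_rep),
             vapply(out$ms[2:4], safe_f, numeric(1), den = ms_res),
             NA_real_)
  dfd <- c(out$df[2], rep(out$df[5], 3), NA)
  out$p <- stats::pf(out$f, out$df, dfd, lower.tail = FALSE)
  out$p[is.infinite(out$f)] <- 0
  structure(out, class = c("met_anova", class(out)),
            dims = d, trait = trait)
}

#' Shares of the three-way sum of squares
#'
#' Percentage of the ENV + GEN + GEN:ENV sum of squares attributable to each
#' term; replicate and residual strata are excluded from the denominator.
#'
#' @param t A `met_anova` table, or any data frame with columns `source` and
#'   `ss` containing rows `ENV`, `GEN` and `GEN:ENV` (e.g. a published ANOVA
#'   table re-keyed for checking).
#' @return One-row tibble with `pct_E`, `pct_G`, `pct_GEI` summing to 100.
#' @export
ss_proportions <- function(t) {
  stopifnot(all(c("source", "ss") %in% names(t)))
  pull_ss <- function(term) {
    v <- t$ss[t$source == term]
    if (length(v) != 1) stop("table lacks a unique '", term, "' row", call. = FALSE)
    v
  }
  sse <- pull_ss("ENV"); ssg <- pull_ss("GEN"); ssi <- pull_ss("GEN:ENV")
  tot <- sse + ssg + ssi
  if (tot == 0) stop("undefined: ENV, GEN and GEN:ENV sums of squares are all zero",
                     call. = FALSE)
  tibble::tibble(pct_E = 100 * sse / tot,
                 pct_G = 100 * ssg / tot,
                 pct_GEI = 100 * ssi / tot)
}

#' Double-center a genotype-by-environment means matrix
#'
#' Removes genotype and environment main effects, leaving the interaction
#' residuals that the AMMI singular value decomposition operates on:
#' `value - gen_mean - env_mean + grand_mean`. All row and column sums of the
#' result are zero.
#'
#' @param m A `ge_matrix` or plain numeric matrix.
#' @return Numeric g x e matrix of interaction residuals.
#' @export
double_center <- function(m) {
  v <- if (inherits(m, "ge_matrix")) m$values else as.matrix(m)
  sweep(sweep(v, 1, rowMeans(v)), 2, colMeans(v)) + mean(v)
}

#' Gollob degrees of freedom for interaction principal components
#'
#' The k-th interaction axis of a g x e table is assigned
#' `g + e - 1 - 2k` degrees of freedom for approximate F-testing.
#'
#' @param g,e Numbers of genotypes and environments.
#' @param k Axis index (vectorized), `1 <= k <= min(g - 1, e - 1)`.
#' @return Integer vector of degrees of freedom.
#' @export
gollob_df <- function(g, e, k) {
  if (any(k < 1 | k > min(g - 1, e - 1))) {
    stop("k out of range 1..min(g-1, e-1)", call. = FALSE)
  }
  as.integer(g + e - 1 - 2 * k)
}

#' Fit the AMMI model
#'
#' Additive main effects and multiplicative interaction: the double-centered
#' cell-means matrix is decomposed by SVD, each axis carries a plot-level sum
#' of squares `r * lambda_k^2`, Gollob degrees of freedom and (when replicate
#' data are available) an F-test against the pooled residual mean square.
#' Genotype scores are `lambda^a * gamma` and environment scores
#' `lambda^(1-a) * delta` with `a = score_scaling`. Axis signs are fixed by
#' making the environment loading of largest magnitude positive (first index
#' on ties), so output is reproducible across SVD implementations.
#'
#' @param x Plot-level MET data frame (F-tests enabled, `r >= 2`) or a
#'   `ge_matrix` (means-only mode: decomposition without F-tests; `r` taken
#'   from the object).
#' @param trait Response column when `x` is a data frame.
#' @param score_scaling Exponent `a` splitting each singular value between
#'   genotype and environment scores; default 0.5 (symmetric).
#' @param sig_level Significance level for declaring axes significant under
#'   the Gollob F-test; default 0.05.
#' @return An `ammi_model`: list with `lambdas`, `gen_scores`, `env_scores`,
#'   `axes` (tibble: axis, df, ss, ms, f, p, prop, accum, significant),
#'   `means` (`ge_matrix`), `anova` (or NULL), `r`, `score_scaling`.
#' @export
fit_ammi <- function(x, trait = "yield", score_scaling = 0.5,
                     sig_level = 0.05) {
  if (is.data.frame(x)) {
    anova_tab <- met_anova(x, trait)
    m <- cell_means(x, trait)
    r <- met_dims(x)$r
    ms_res <- anova_tab$ms[anova_tab$source == "Residuals"]
    df_res <- anova_tab$df[anova_tab$source == "Residuals"]
  } else if (inherits(x, "ge_matrix")) {
    anova_tab <- NULL
    m <- x
    r <- x$r
    ms_res <- NA_real_
    df_res <- NA_integer_
  } else {
    stop("x must be a MET data frame or a ge_matrix", call. = FALSE)
  }
  g <- nrow(m$values); e <- ncol(m$values)
  p <- min(g - 1, e - 1)
  dc <- double_center(m)
  sv <- svd(dc, nu = p, nv = p)
  lam <- sv$d[seq_len(p)]
  u <- sv$u; v <- sv$v
  # sign rule: largest-magnitude environment loading positive per axis
  for (k in seq_len(p)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  axis_ss <- r * lam^2
  ss_gei <- sum(axis_ss)
  axis_df <- gollob_df(g, e, seq_len(p))
  axis_ms <- axis_ss / axis_df
  axis_f <- if (is.na(ms_res)) rep(NA_real_, p) else axis_ms / ms_res
  axis_p <- if (is.na(ms_res)) rep(NA_real_, p) else
    stats::pf(axis_f, axis_df, df_res, lower.tail = FALSE)
  prop <- if (ss_gei > 0) 100 * axis_ss / ss_gei else rep(0, p)
  axes <- tibble::tibble(
    axis = paste0("PC", seq_len(p)),
    df = axis_df, ss = axis_ss, ms = axis_ms,
    f = axis_f, p = axis_p,
    prop = prop, accum = cumsum(prop),
    significant = !is.na(axis_p) & axis_p < sig_level)
  a <- score_scaling
  gen_scores <- u %*% diag(lam^a, p)
  env_scores <- v %*% diag(lam^(1 - a), p)
  dimnames(gen_scores) <- list(rownames(m$values), axes$axis)
  dimnames(env_scores) <- list(colnames(m$values), axes$axis)
  structure(
    list(lambdas = lam, gen_scores = gen_scores, env_scores = env_scores,
         axes = axes, means = m, anova = anova_tab, r = r,
         score_scaling = score_scaling, sig_level = sig_level),
    class = "ammi_model")
}

#' @export
print.ammi_model <- function(x, ...) {
  cat(sprintf("<ammi_model> %d genotypes x %d environments, %d axes (score scaling %.2g)\n",
              nrow(x$gen_scores), nrow(x$env_scores), length(x$lambdas),
              x$score_scaling))
  print(x$axes)
  invisible(x)
}

#' Tidy an AMMI model: the per-axis table
#'
#' @param x An `ammi_model`.
#' @param ... Unused.
#' @return Tibble with one row per interaction axis (df, SS, MS, F, p,
#'   percent and cumulative percent of GEI, significance flag).
#' @export
tidy.ammi_model <- function(x, ...) x$axes

#' One-row summary of an AMMI fit
#'
#' @param x An `ammi_model`.
#' @param ... Unused.
#' @return Tibble with design sizes, interaction SS, number of significant
#'   axes and the percent of GEI on the first two axes.
#' @export
glance.ammi_model <- function(x, ...) {
  tibble::tibble(
    g = nrow(x$gen_scores), e = nrow(x$env_scores), r = x$r,
    ss_gei = sum(x$axes$ss),
    n_sig_axes = sum(x$axes$significant),
    pc1_pct = x$axes$prop[1],
    pc12_pct = if (nrow(x$axes) >= 2) x$axes$accum[2] else x$axes$accum[1])
}

#' AMMI1 biplot coordinates (mean yield vs IPCA1)
#'
#' @param model An `ammi_model`.
#' @return Tibble with `label`, `role` (genotype/environment), `x` (mean
#'   yield) and `y` (IPCA1 score), one row per genotype and environment.
#' @export
ammi1_coords <- function(model) {
  stopifnot(inherits(model, "ammi_model"))
  m <- model$means
  tibble::tibble(
    label = c(rownames(model$gen_scores), rownames(model$env_scores)),
    role = rep(c("genotype", "environment"),
               c(nrow(model$gen_scores), nrow(model$env_scores))),
    x = c(unname(m$gen_means), unname(m$env_means)),
    y = unname(c(model$gen_scores[, 1], model$env_scores[, 1])))
}

#' AMMI2 biplot coordinates (IPCA1 vs IPCA2)
#'
#' @param model An `ammi_model` with at least two axes.
#' @return Tibble with `label`, `role`, `x` (IPCA1), `y` (IPCA2).
#' @export
ammi2_coords <- function(model) {
  stopifnot(inherits(model, "ammi_model"))
  if (length(model$lambdas) < 2) {
    stop("AMMI2 biplot needs at least 2 interaction axes", call. = FALSE)
  }
  tibble::tibble(
    label = c(rownames(model$gen_scores), rownames(model$env_scores)),
    role = rep(c("genotype", "environment"),
               c(nrow(model$gen_scores), nrow(model$env_scores))),
    x = unname(c(model$gen_scores[, 1], model$env_scores[, 1])),
    y = unname(c(model$gen_scores[, 2], model$env_scores[, 2])))
}

#' Plot an AMMI biplot
#'
#' @param object An `ammi_model`.
#' @param type `"AMMI1"` (mean vs IPCA1) or `"AMMI2"` (IPCA1 vs IPCA2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ammi_model <- function(object, type = c("AMMI1", "AMMI2"), ...) {
  type <- match.arg(type)
  co <- if (type == "AMMI1") ammi1_coords(object) else ammi2_coords(object)
  labs <- if (type == "AMMI1") {
    ggplot2::labs(x = "Mean yield (g m⁻²)",
                  y = sprintf("IPCA1 (%.1f%% of GEI)", object$axes$prop[1]))
  } else {
    ggplot2::labs(x = sprintf("IPCA1 (%.1f%% of GEI)", object$axes$prop[1]),
                  y = sprintf("IPCA2 (%.1f%% of GEI)", object$axes$prop[2]))
  }
  ggplot2::ggplot(co, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$role, label = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    {if (type == "AMMI2") ggplot2::geom_vline(xintercept = 0, linetype = 2,
                                              colour = "grey60")} +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    labs +
    ggplot2::theme_minimal()
}
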