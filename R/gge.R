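#' Fit the GGE model
#'
#' Environment-centered singular value decomposition of the cell-means
#' matrix: genotype main effects and genotype-by-environment interaction are
#' retained together (`y_ij - env_mean_j`, optionally divided by the
#' environment standard deviation), and the first two axes give the biplot.
#' Singular values are partitioned between genotype and environment
#' coordinates according to `svp`.
#'
#' @param x A `ge_matrix` or plot-level MET data frame.
#' @param trait Response column when `x` is a data frame.
#' @param scaling `"none"` (centering only, default) or `"sd"` (divide each
#'   centered column by its standard deviation).
#' @param svp Singular value partitioning: `"symmetric"` (both sides carry
#'   `lambda^0.5`; default, suits the which-won-where view), `"genotype"`
#'   (genotype coordinates carry `lambda`; suits mean-vs-stability) or
#'   `"environment"`.
#' @return A `gge_model`: list with `centered` (g x e matrix), `svd`,
#'   `gen_coords` and `env_coords` (g x 2 / e x 2), `pct_explained` (per axis,
#'   all axes), `svp`, `scaling`.
#' @export
fit_gge <- function(x, trait = "yield", scaling = c("none", "sd"),
                    svp = c("symmetric", "genotype", "environment")) {
  scaling <- match.arg(scaling)
  svp <- match.arg(svp)
  m <- if (is.data.frame(x)) cell_means(x, trait) else x
  stopifnot(inherits(m, "ge_matrix"))
  centered <- sweep(m$values, 2, m$env_means)
  if (scaling == "sd") {
    sds <- apply(m$values, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance environment(s) with sd scaling: ",
           paste(colnames(m$values)[sds == 0], collapse = ", "), call. = FALSE)
    }
    centered <- sweep(centered, 2, sds, `/`)
  }
  sv <- svd(centered)
  # sign rule as in the AMMI fit: largest |env loading| positive
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  d2 <- sv$d^2
  pct <- if (sum(d2) > 0) 100 * d2 / sum(d2) else rep(0, length(d2))
  lam <- sv$d[1:2]
  powers <- switch(svp,
                   symmetric = c(0.5, 0.5),
                   genotype = c(1, 0),
                   environment = c(0, 1))
  gen_coords <- sv$u[, 1:2, drop = FALSE] %*% diag(lam^powers[1], 2)
  env_coords <- sv$v[, 1:2, drop = FALSE] %*% diag(lam^powers[2], 2)
  dimnames(gen_coords) <- list(rownames(m$values), c("PC1", "PC2"))
  dimnames(env_coords) <- list(colnames(m$values), c("PC1", "PC2"))
  structure(
    list(centered = centered, svd = sv, gen_coords = gen_coords,
         env_coords = env_coords, pct_explained = pct,
         svp = svp, scaling = scaling, means = m),
    class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  cat(sprintf("<gge_model> %d genotypes x %d environments; svp = %s, scaling = %s\n",
              nrow(x$gen_coords), nrow(x$env_coords), x$svp, x$scaling))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of G + GEI\n",
              x$pct_explained[1], x$pct_explained[2]))
  invisible(x)
}

#' Tidy a GGE model: the biplot coordinates
#'
#' @param x A `gge_model`.
#' @param ... Unused.
#' @return Tibble with `label`, `role`, `PC1`, `PC2`.
#' @export
tidy.gge_model <- function(x, ...) {
  tibble::tibble(
    label = c(rownames(x$gen_coords), rownames(x$env_coords)),
    role = rep(c("genotype", "environment"),
               c(nrow(x$gen_coords), nrow(x$env_coords))),
    PC1 = unname(c(x$gen_coords[, 1], x$env_coords[, 1])),
    PC2 = unname(c(x$gen_coords[, 2], x$env_coords[, 2])))
}

#' Which-won-where analysis of a GGE biplot
#'
#' Draws the convex hull ("polygon") around the genotype points; rays from
#' the origin perpendicular to the hull edges split the plane into sectors,
#' and each environment belongs to the sector of the hull vertex that
#' maximizes its inner product — equivalently, the genotype the rank-2 model
#' predicts to win that environment. Environments exactly on a boundary go to
#' the lower-indexed sector.
#'
#' @param model A `gge_model`.
#' @return A `www_result`: list with `hull_vertices` (genotype labels in hull
#'   order), `sectors` (tibble: `env`, `sector`, `winner`) and
#'   `winner_of_sector` (tibble: `sector`, `winner`).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  gc <- model$gen_coords
  if (nrow(gc) < 3) stop("need at least 3 genotypes", call. = FALSE)
  hull_idx <- grDevices::chull(gc[, 1], gc[, 2])
  if (length(hull_idx) < 3) {
    stop("degenerate geometry: genotype points are collinear or coincident",
         call. = FALSE)
  }
  hull <- rownames(gc)[hull_idx]
  ec <- model$env_coords
  # winner of each environment: hull vertex maximizing the inner product
  # (the max of a linear functional over all genotype points is attained at a
  # hull vertex); boundary ties resolved to the lower hull index
  winner_idx <- vapply(seq_len(nrow(ec)), function(j) {
    dots <- gc[hull_idx, , drop = FALSE] %*% ec[j, ]
    hull_pos <- which(dots >= max(dots) - 1e-12)[1]
    hull_pos
  }, integer(1))
  sectors <- tibble::tibble(
    env = rownames(ec),
    sector = winner_idx,
    winner = hull[winner_idx])
  occupied <- sort(unique(winner_idx))
  structure(
    list(hull_vertices = hull,
         sectors = sectors,
         winner_of_sector = tibble::tibble(sector = occupied,
                                           winner = hull[occupied])),
    class = "www_result")
}

#' @export
print.www_result <- function(x, ...) {
  cat("<which-won-where>\n hull:", paste(x$hull_vertices, collapse = " "), "\n")
  print(x$sectors)
  invisible(x)
}

#' Mean performance versus stability projection
#'
#' Projects each genotype onto the average environment axis (AEA, the
#' direction of the mean environment point): the projection is the modeled
#' mean performance, the signed perpendicular component (along the average
#' ordinate environment, AOE) measures instability, and genotypes are ranked
#' by Euclidean distance to the "ideal" point — the point on the AEA at the
#' largest observed projection.
#'
#' @param model A `gge_model` (genotype-focused SVP recommended).
#' @return An `aea_projection` tibble with `gen`, `mean_proj`, `stab_dist`
#'   (signed), `dist_to_ideal`, `rank`; attributes `aea_direction` and
#'   `ideal_point`.
#' @export
mean_vs_stability <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  avg_env <- colMeans(model$env_coords)
  nrm <- sqrt(sum(avg_env^2))
  if (nrm < 1e-12) {
    stop("undefined AEA: mean environment coordinate is at the origin",
         call. = FALSE)
  }
  aea <- avg_env / nrm
  aoe <- c(-aea[2], aea[1])
  gc <- model$gen_coords
  mean_proj <- as.vector(gc %*% aea)
  stab_dist <- as.vector(gc %*% aoe)
  ideal <- aea * max(mean_proj)
  dist_to_ideal <- sqrt((gc[, 1] - ideal[1])^2 + (gc[, 2] - ideal[2])^2)
  out <- tibble::tibble(
    gen = rownames(gc),
    mean_proj = unname(mean_proj),
    stab_dist = unname(stab_dist),
    dist_to_ideal = unname(dist_to_ideal),
    rank = unname(avg_rank(dist_to_ideal)))
  attr(out, "aea_direction") <- aea
  attr(out, "ideal_point") <- ideal
  class(out) <- c("aea_projection", class(out))
  out
}

#' Rank genotypes against the ideal genotype
#'
#' Convenience wrapper around [mean_vs_stability()] returning genotypes in
#' rank order (rank 1 = closest to the ideal point).
#'
#' @param model A `gge_model`.
#' @return Tibble sorted by rank.
#' @export
rank_genotypes <- function(model) {
  dplyr::arrange(mean_vs_stability(model), .data$rank)
}

#' Plot a GGE biplot view
#'
#' @param object A `gge_model`.
#' @param type `"www"` (which-won-where polygon) or `"mean_stability"`
#'   (AEA/AOE axes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gge_model <- function(object, type = c("www", "mean_stability"), ...) {
  type <- match.arg(type)
  co <- tidy(object)
  p <- ggplot2::ggplot(co, ggplot2::aes(.data$PC1, .data$PC2,
                                        colour = .data$role,
                                        label = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", object$pct_explained[1]),
                  y = sprintf("PC2 (%.1f%%)", object$pct_explained[2])) +
    ggplot2::theme_minimal()
  if (type == "www") {
    www <- which_won_where(object)
    hull <- object$gen_coords[www$hull_vertices, , drop = FALSE]
    hull_df <- tibble::tibble(PC1 = hull[, 1], PC2 = hull[, 2])
    p <- p + ggplot2::geom_polygon(data = hull_df,
                                   ggplot2::aes(.data$PC1, .data$PC2),
                                   inherit.aes = FALSE,
                                   fill = NA, colour = "grey40")
  } else {
    ms <- mean_vs_stability(object)
    aea <- attr(ms, "aea_direction")
    lim <- max(abs(c(co$PC1, co$PC2)))
    aea_df <- tibble::tibble(x = c(-lim, lim) * aea[1],
                             y = c(-lim, lim) * aea[2])
    aoe_df <- tibble::tibble(x = c(-lim, lim) * -aea[2],
                             y = c(-lim, lim) * aea[1])
    p <- p +
      ggplot2::geom_path(data = aea_df, ggplot2::aes(.data$x, .data$y),
                         inherit.aes = FALSE, colour = "steelblue",
                         arrow = grid::arrow(length = grid::unit(3, "mm"))) +
      ggplot2::geom_path(data = aoe_df, ggplot2::aes(.data$x, .data$y),
                         inherit.aes = FALSE, colour = "steelblue",
                         linetype = 3)
  }
  p
}
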