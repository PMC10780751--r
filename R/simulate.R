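#' Simulate a balanced multi-environment trial
#'
#' Generates plot-level data from the two-way mixed additive/multiplicative
#' model
#' \deqn{y_{ger} = \mu + \alpha_g + \beta_e + \sum_k \lambda_k \gamma_{gk}
#'   \delta_{ek} + b_{r(e)} + \varepsilon_{ger}}
#' with genotype and environment main effects drawn centered and then
#' rescaled exactly so the true-effect sums of squares hit the requested
#' partition of the G + E + GEI total, and a low-rank GEI built from
#' orthonormal axis pairs whose squared singular values follow
#' `gei_axis_weights`. Every realized effect is returned as ground truth, so
#' recovery by the ANOVA/AMMI pipeline can be tested.
#'
#' Defaults are the package's reference study conditions, typical of a rice
#' MET run at 4 locations over 2 seasons: 34 genotypes, 8 environments, 3
#' blocks; environments carry 71.29%, genotypes 14.77% and the interaction
#' 13.94% of the three-way sum of squares, with the first four interaction
#' axes holding 88.9/7.9/2.2/1.0% of the GEI.
#'
#' @param g,e,r Numbers of genotypes, environments, replicates (blocks per
#'   environment).
#' @param ss_fractions Length-3 numeric `(f_E, f_G, f_GEI)` summing to 1:
#'   shares of the true-effect sum of squares.
#' @param gei_rank Number of multiplicative interaction axes
#'   (`<= min(g - 1, e - 1)`); default `min(4, g - 1, e - 1)`.
#' @param gei_axis_weights Fractions of the GEI sum of squares per axis,
#'   length `gei_rank`, summing to 1, non-increasing. Default: the reference
#'   four-axis profile `(0.889, 0.079, 0.022, 0.010)`, truncated and
#'   renormalized when `gei_rank < 4`.
#' @param block_sd Standard deviation of replicate (block-within-environment)
#'   effects, g m^-2.
#' @param noise_sd Plot residual standard deviation, g m^-2.
#' @param grand_mean Overall mean yield, g m^-2.
#' @param total_ss Target true-effect sum of squares for E + G + GEI at plot
#'   level; default scales a per-plot mean square of 55,000 (g m^-2)^2 by the
#'   number of plots, which reproduces field-scale yield dispersion for the
#'   default design.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list with `data` (plot-level tibble: `env`, `gen`, `rep`,
#'   `yield`) and `truth` (list of every generated effect: `alpha`, `beta`,
#'   `lambda`, `gamma`, `delta`, `block`, `ss`, `fractions`).
#' @export
simulate_met <- function(g = 34, e = 8, r = 3,
                         ss_fractions = c(0.7129, 0.1477, 0.1394),
                         gei_rank = NULL,
                         gei_axis_weights = NULL,
                         block_sd = 3.2, noise_sd = 22,
                         grand_mean = 700,
                         total_ss = 55000 * g * e * r,
                         seed = 1L) {
  stopifnot(g >= 3, e >= 2, r >= 1, block_sd >= 0, noise_sd >= 0)
  ss_fractions <- as.numeric(ss_fractions)
  if (length(ss_fractions) != 3 || any(ss_fractions < 0) ||
      abs(sum(ss_fractions) - 1) > 1e-8) {
    stop("ss_fractions must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  }
  f_E <- ss_fractions[1]; f_G <- ss_fractions[2]; f_GEI <- ss_fractions[3]
  if (is.null(gei_rank)) gei_rank <- min(4, g - 1, e - 1)
  if (is.null(gei_axis_weights)) {
    w0 <- utils::head(c(0.889, 0.079, 0.022, 0.010), gei_rank)
    gei_axis_weights <- w0 / sum(w0)
  }
  if (f_GEI > 0) {
    if (gei_rank < 1 || gei_rank > min(g - 1, e - 1)) {
      stop("config error: gei_rank must be in 1..min(g-1, e-1)", call. = FALSE)
    }
    w <- as.numeric(gei_axis_weights)
    if (length(w) != gei_rank || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("config error: gei_axis_weights must be length gei_rank, ",
           "non-negative, summing to 1", call. = FALSE)
    }
  } else {
    gei_rank <- 0L
    w <- numeric(0)
  }

  gens <- sprintf("G%0*d", nchar(g), seq_len(g))
  envs <- sprintf("E%0*d", nchar(e), seq_len(e))
  reps <- sprintf("R%d", seq_len(r))

  local_seed(seed, {
    # main effects: draw, center, rescale to exact SS share
    alpha <- stats::rnorm(g)
    alpha <- alpha - mean(alpha)
    if (f_G > 0) alpha <- alpha * sqrt(f_G * total_ss / (e * r * sum(alpha^2)))
    else alpha <- rep(0, g)
    beta <- stats::rnorm(e)
    beta <- beta - mean(beta)
    if (f_E > 0) beta <- beta * sqrt(f_E * total_ss / (g * r * sum(beta^2)))
    else beta <- rep(0, e)

    # low-rank interaction on orthonormal, column-centered axis pairs
    if (gei_rank > 0) {
      gamma <- qr.Q(qr(scale(matrix(stats::rnorm(g * gei_rank), g),
                             center = TRUE, scale = FALSE)))[, seq_len(gei_rank),
                                                             drop = FALSE]
      delta <- qr.Q(qr(scale(matrix(stats::rnorm(e * gei_rank), e),
                             center = TRUE, scale = FALSE)))[, seq_len(gei_rank),
                                                             drop = FALSE]
      lambda <- sqrt(w * f_GEI * total_ss / r)
      flips <- sample(c(-1, 1), gei_rank, replace = TRUE)
      gamma <- sweep(gamma, 2, flips, `*`)
      delta <- sweep(delta, 2, flips, `*`)
      interaction <- gamma %*% diag(lambda, gei_rank) %*% t(delta)
    } else {
      gamma <- matrix(0, g, 0); delta <- matrix(0, e, 0)
      lambda <- numeric(0)
      interaction <- matrix(0, g, e)
    }
    dimnames(interaction) <- list(gens, envs)

    # blocks centered within environment so they do not leak into ENV SS
    block <- matrix(stats::rnorm(e * r, 0, block_sd), e, r,
                    dimnames = list(envs, reps))
    if (r > 1) block <- block - rowMeans(block)
    else block[] <- 0

    grid <- tidyr::expand_grid(env = envs, gen = gens, rep = reps)
    gi <- match(grid$gen, gens)
    ei <- match(grid$env, envs)
    ri <- match(grid$rep, reps)
    eps <- stats::rnorm(nrow(grid), 0, noise_sd)
    grid$yield <- grand_mean + alpha[gi] + beta[ei] +
      interaction[cbind(gi, ei)] + block[cbind(ei, ri)] + eps

    truth <- list(
      grand_mean = grand_mean,
      alpha = stats::setNames(alpha, gens),
      beta = stats::setNames(beta, envs),
      lambda = lambda,
      gamma = `dimnames<-`(gamma, list(gens, NULL)),
      delta = `dimnames<-`(delta, list(envs, NULL)),
      block = block,
      ss = c(E = g * r * sum(beta^2),
             G = e * r * sum(alpha^2),
             GEI = r * sum(interaction^2)),
      fractions = c(f_E = f_E, f_G = f_G, f_GEI = f_GEI))
    list(data = grid, truth = truth)
  })
}

#' Add secondary traits with target Spearman correlations to yield
#'
#' Traits are generated by a rank-preserving Gaussian-copula construction:
#' the yield column is mapped to normal scores, each trait's latent variable
#' is a mixture of that score and independent noise with the Pearson
#' correlation `2 sin(pi * rho / 6)` that corresponds to the requested
#' Spearman `rho` under bivariate normality, and the trait is a linear
#' (hence rank-preserving) transform of the latent variable.
#'
#' Defaults emulate a rice MET where yield correlates with panicle length
#' (`PL`, rho 0.825), panicles per plant (`NPP`, rho 0.904), thousand-grain
#' weight (`TG`, rho 0.491) and negatively with sterility percentage (`ST`).
#'
#' @param data MET tibble with a `yield` column.
#' @param traits Data frame with columns `trait`, `rho` (target Spearman,
#'   in \[-1, 1\]), `mean`, `sd`, and optional `noise_sd` (latent noise
#'   loading; `NA` derives the value that hits the target correlation).
#' @param seed Integer seed.
#' @return `data` with one numeric column per trait appended.
#' @export
simulate_traits <- function(data,
                            traits = default_trait_config(),
                            seed = 1L) {
  stopifnot("yield" %in% names(data))
  stopifnot(all(c("trait", "rho", "mean", "sd") %in% names(traits)))
  if (any(abs(traits$rho) > 1)) {
    stop("config error: target Spearman rho must lie in [-1, 1]", call. = FALSE)
  }
  n <- nrow(data)
  z_y <- stats::qnorm((rank(data$yield, ties.method = "average") - 0.5) / n)
  local_seed(seed, {
    for (i in seq_len(nrow(traits))) {
      rho_s <- traits$rho[i]
      rho_p <- if (abs(rho_s) == 1) rho_s else 2 * sin(pi * rho_s / 6)
      noise_sd <- if ("noise_sd" %in% names(traits) && !is.na(traits$noise_sd[i])) {
        traits$noise_sd[i]
      } else {
        sqrt(max(0, 1 - rho_p^2))
      }
      if (abs(rho_s) == 1 && noise_sd > 0) {
        stop("config error: |rho| = 1 is incompatible with positive trait noise",
             call. = FALSE)
      }
      latent <- rho_p * z_y + noise_sd * stats::rnorm(n)
      data[[traits$trait[i]]] <- traits$mean[i] + traits$sd[i] * latent
    }
    tibble::as_tibble(data)
  })
}

#' Default secondary-trait configuration
#'
#' @return Tibble with columns `trait`, `rho`, `mean`, `sd` for panicle
#'   length (cm), panicles per plant, thousand-grain weight (g) and
#'   sterility (%).
#' @export
default_trait_config <- function() {
  tibble::tibble(
    trait = c("PL", "NPP", "TG", "ST"),
    rho = c(0.825, 0.904, 0.491, -0.6),
    mean = c(22, 18, 24, 12),
    sd = c(2, 3, 2.5, 4))
}

#' Realized sums-of-squares fractions of a MET dataset
#'
#' Shares of ENV, GEN and GEN:ENV over their three-way sum-of-squares total
#' (replicate and residual strata excluded), as fractions. Delegates to
#' [met_anova()].
#'
#' @param data Plot-level MET tibble with `r >= 2` replicates.
#' @return Named numeric vector `(f_E, f_G, f_GEI)` summing to 1.
#' @export
realized_ss_fractions <- function(data) {
  p <- ss_proportions(met_anova(data))
  c(f_E = p$pct_E, f_G = p$pct_G, f_GEI = p$pct_GEI) / 100
}
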