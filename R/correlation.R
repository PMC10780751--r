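#' Spearman correlation matrix of yield and secondary traits
#'
#' Rank correlations (average ranks on ties) between every pair of the
#' selected columns, with p-values from the t-distribution approximation on
#' `n - 2` degrees of freedom and conventional significance stars
#' (* <= 0.05, ** <= 0.01, *** <= 0.001; no multiplicity adjustment).
#' Pooled scope concatenates all environments at plot level (mixing between-
#' and within-environment variation); per-environment scope returns one
#' matrix per environment; genotype-mean level averages plots per genotype
#' first.
#'
#' @param data Plot-level MET tibble.
#' @param traits Columns to correlate; defaults to `yield` plus every numeric
#'   column other than the design columns.
#' @param scope `"pooled"` (default) or `"per_env"`.
#' @param level `"plot"` (default) or `"genotype_mean"`.
#' @return A `corr_matrix` (list with `rho`, `p`, `stars`, `n`), or a named
#'   list of them for `scope = "per_env"`.
#' @export
spearman_matrix <- function(data, traits = NULL,
                            scope = c("pooled", "per_env"),
                            level = c("plot", "genotype_mean")) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c("env", "gen", "rep"))
    traits <- union("yield", traits)
  }
  miss <- setdiff(traits, names(data))
  if (length(miss) > 0) stop("unknown trait(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  if (scope == "per_env") {
    out <- lapply(split(data, data$env), spearman_one,
                  traits = traits, level = level)
    return(out[sort(names(out))])
  }
  spearman_one(data, traits, level)
}

spearman_one <- function(data, traits, level) {
  if (level == "genotype_mean") {
    data <- dplyr::summarise(dplyr::group_by(data, .data$gen),
                             dplyr::across(dplyr::all_of(traits), mean),
                             .groups = "drop")
  }
  x <- as.matrix(data[traits])
  n <- nrow(x)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  diag(p) <- NA
  structure(list(rho = rho, p = p,
                 stars = matrix(p_stars(p), nrow(p), dimnames = dimnames(p)),
                 n = n),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<corr_matrix> Spearman rho, n = %d\n", x$n))
  shown <- matrix(paste0(format(round(x$rho, digits)), x$stars),
                  nrow(x$rho), dimnames = dimnames(x$rho))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Tidy a correlation matrix into long format
#'
#' @param x A `corr_matrix`.
#' @param ... Unused.
#' @return Tibble with `trait1`, `trait2`, `rho`, `p`, `stars` for each
#'   unordered pair.
#' @export
tidy.corr_matrix <- function(x, ...) {
  nm <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(trait1 = nm[idx[, 1]], trait2 = nm[idx[, 2]],
                 rho = x$rho[idx], p = x$p[idx],
                 stars = x$stars[idx])
}
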