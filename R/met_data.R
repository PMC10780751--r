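#' Read a multi-environment trial table from CSV
#'
#' Reads plot-level MET data laid out as a balanced randomized complete block
#' design (RCBD): one row per plot, with environment, genotype, replicate and
#' yield columns plus any number of secondary trait columns. Column names in
#' the file are mapped to the canonical names `env`, `gen`, `rep`, `yield`
#' through `schema`.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param schema Named character vector mapping canonical names to file
#'   columns, e.g. `c(env = "ENV", gen = "GEN", rep = "REP", yield = "YLD")`.
#'   Defaults to the canonical upper-case convention. Columns of the file not
#'   named in the schema are carried along as traits.
#' @return A tibble with columns `env`, `gen`, `rep` (character), `yield`
#'   (double, g m^-2) and any trait columns, validated for balance.
#' @seealso [validate_met()], [write_met_table()], [cell_means()]
#' @export
read_met_table <- function(path,
                           schema = c(env = "ENV", gen = "GEN",
                                      rep = "REP", yield = "YLD")) {
  stopifnot(length(path) == 1, file.exists(path))
  need <- c("env", "gen", "rep", "yield")
  if (!all(need %in% names(schema))) {
    stop("schema must name columns for: ",
         paste(setdiff(need, names(schema)), collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw
  names(out)[match(unname(schema), names(out))] <- names(schema)
  if (!is.numeric(out$yield)) {
    bad <- which(is.na(suppressWarnings(as.numeric(out$yield))))
    stop("parse error: non-numeric yield at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(out)
  out$env <- as.character(out$env)
  out$gen <- as.character(out$gen)
  out$rep <- as.character(out$rep)
  validate_met(out)
}

#' Write a MET table to CSV
#'
#' Inverse of [read_met_table()]: writes the canonical CSV dialect (UTF-8,
#' header, no row names, no quoting of plain labels) so that a read/write
#' cycle round-trips byte-identically.
#'
#' @param data MET tibble as returned by [read_met_table()] or [simulate_met()].
#' @param path Output file path.
#' @param schema Named character vector as in [read_met_table()]; canonical
#'   columns are renamed back before writing.
#' @return `path`, invisibly.
#' @export
write_met_table <- function(data, path,
                            schema = c(env = "ENV", gen = "GEN",
                                       rep = "REP", yield = "YLD")) {
  out <- as.data.frame(data)
  idx <- match(names(schema), names(out))
  names(out)[idx[!is.na(idx)]] <- unname(schema)[!is.na(idx)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a MET data frame
#'
#' Checks the invariants every downstream analysis relies on: canonical
#' columns present, yields finite and non-negative, every
#' (environment, genotype) cell filled with exactly `r` replicates
#' (balanced RCBD, no duplicated plots), at least 3 genotypes and 2
#' environments.
#'
#' @param data Data frame with columns `env`, `gen`, `rep`, `yield`.
#' @return The data as a tibble, invisibly usable in a pipe.
#' @export
validate_met <- function(data) {
  need <- c("env", "gen", "rep", "yield")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(data$yield)) || any(data$yield < 0)) {
    stop("yield values must be finite and >= 0", call. = FALSE)
  }
  d <- met_dims(data)
  if (d$g < 3) stop("need at least 3 genotypes (g >= 3)", call. = FALSE)
  if (d$e < 2) stop("need at least 2 environments (e >= 2)", call. = FALSE)
  counts <- dplyr::count(data, .data$env, .data$gen)
  if (any(counts$n != d$r) || nrow(counts) != d$g * d$e) {
    full <- tidyr::expand_grid(env = unique(data$env), gen = unique(data$gen))
    counts <- dplyr::left_join(full, counts, by = c("env", "gen"))
    counts$n[is.na(counts$n)] <- 0L
    bad <- counts[counts$n != d$r, ]
    stop("balance error: cell(s) without exactly r = ", d$r,
         " replicates: ",
         paste(sprintf("(%s, %s): %d", bad$env, bad$gen, bad$n)[
           seq_len(min(5, nrow(bad)))], collapse = "; "),
         call. = FALSE)
  }
  dup <- dplyr::count(data, .data$env, .data$gen, .data$rep)
  if (any(dup$n > 1)) {
    stop("balance error: duplicated (env, gen, rep) plot records", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Design dimensions of a MET table
#'
#' @param data MET data frame.
#' @return A list with counts `g` (genotypes), `e` (environments),
#'   `r` (replicates per cell).
#' @export
met_dims <- function(data) {
  g <- length(unique(data$gen))
  e <- length(unique(data$env))
  r <- as.integer(round(nrow(data) / (g * e)))
  list(g = g, e = e, r = max(r, 1L))
}

#' Genotype-by-environment cell-means matrix
#'
#' Averages replicates within each (genotype, environment) cell and returns
#' the g x e means matrix together with its marginal means — the substrate of
#' every AMMI/GGE decomposition and of all stability statistics.
#'
#' @param data MET data frame (see [validate_met()]).
#' @param trait Column to average; default `"yield"`.
#' @return A `ge_matrix` object: list with `values` (g x e matrix, genotypes
#'   as rows), `gen_means`, `env_means`, `grand_mean` and `r` (replicates the
#'   means were taken over).
#' @export
cell_means <- function(data, trait = "yield") {
  if (!trait %in% names(data)) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  assert_balanced(data)
  gens <- sort(unique(data$gen))
  envs <- sort(unique(data$env))
  m <- tapply(data[[trait]], list(factor(data$gen, gens), factor(data$env, envs)),
              mean)
  m <- matrix(as.numeric(m), nrow = length(gens),
              dimnames = list(gens, envs))
  new_ge_matrix(m, r = met_dims(data)$r)
}

#' Construct a ge_matrix from a plain matrix
#'
#' Used directly in hand-sized worked examples where only the cell means are
#' known (r = 1, means-only mode).
#'
#' @param values Numeric g x e matrix; rows = genotypes, cols = environments.
#' @param r Number of replicates behind each cell mean (default 1).
#' @return A `ge_matrix`.
#' @export
new_ge_matrix <- function(values, r = 1L) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("E%d", seq_len(ncol(values)))
  }
  structure(
    list(values = values,
         gen_means = rowMeans(values),
         env_means = colMeans(values),
         grand_mean = mean(values),
         r = as.integer(r)),
    class = "ge_matrix")
}

#' @export
print.ge_matrix <- function(x, ...) {
  cat(sprintf("<ge_matrix> %d genotypes x %d environments (cell means of %d rep%s)\n",
              nrow(x$values), ncol(x$values), x$r, if (x$r > 1) "s" else ""))
  cat(sprintf("grand mean %.4g; env means %.4g..%.4g\n",
              x$grand_mean, min(x$env_means), max(x$env_means)))
  print(utils::head(x$values, 6))
  invisible(x)
}

#' @export
as.matrix.ge_matrix <- function(x, ...) x$values

#' Tidy a ge_matrix into long format
#'
#' @param x A `ge_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gen`, `env`, `value`.
#' @export
tidy.ge_matrix <- function(x, ...) {
  tibble::tibble(
    gen = rep(rownames(x$values), times = ncol(x$values)),
    env = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values))
}

#' Write a ge_matrix as TSV
#'
#' Genotypes as rows, environments as columns, marginal means appended as a
#' labeled extra row (`ENV_MEAN`) and column (`GEN_MEAN`).
#'
#' @param x A `ge_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ge_matrix <- function(x, path) {
  m <- cbind(x$values, GEN_MEAN = x$gen_means)
  m <- rbind(m, ENV_MEAN = c(x$env_means, x$grand_mean))
  df <- data.frame(gen = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify environments as favorable or unfavorable
#'
#' An environment is favorable when its mean yield exceeds the grand mean;
#' environments exactly at the grand mean are classified unfavorable (a
#' deterministic tie rule). The split feeds the favorable/unfavorable
#' variants of the Annicchiarico and Lin-Binns statistics.
#'
#' @param m A `ge_matrix` (or MET data frame, in which case yield cell means
#'   are computed first).
#' @return Tibble with columns `env`, `env_mean`, `class`
#'   (`"favorable"`/`"unfavorable"`).
#' @export
classify_environments <- function(m) {
  if (is.data.frame(m)) m <- cell_means(m)
  stopifnot(inherits(m, "ge_matrix"))
  tibble::tibble(
    env = colnames(m$values),
    env_mean = unname(m$env_means),
    class = unname(ifelse(m$env_means > m$grand_mean,
                          "favorable", "unfavorable")))
}
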