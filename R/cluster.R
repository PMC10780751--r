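#' Squared Euclidean distances between genotype rank profiles
#'
#' @param p Numeric matrix or data frame of rank profiles (genotypes as rows,
#'   one column per stability-index rank). Columns that are entirely `NA`
#'   are dropped with a warning; any remaining `NA` is an error.
#' @return A `dist` object of squared Euclidean distances.
#' @export
rank_distance <- function(p) {
  if (is.data.frame(p)) {
    rn <- if ("gen" %in% names(p)) p$gen else rownames(p)
    p <- as.matrix(p[vapply(p, is.numeric, logical(1))])
    rownames(p) <- rn
  }
  if (nrow(p) < 2) stop("need at least 2 genotypes", call. = FALSE)
  all_na <- apply(p, 2, function(x) all(is.na(x)))
  if (any(all_na)) {
    warning("dropping all-NA rank column(s): ",
            paste(colnames(p)[all_na], collapse = ", "))
    p <- p[, !all_na, drop = FALSE]
  }
  if (anyNA(p)) stop("rank profiles contain missing values", call. = FALSE)
  stats::dist(p, method = "euclidean")^2
}

#' Ward clustering of rank profiles
#'
#' Agglomerates genotypes by Ward's minimum-variance criterion. The classical
#' criterion operates on squared Euclidean distances (`method = "classical"`,
#' default, using `hclust`'s `"ward.D"` linkage on the squared distances as
#' produced by [rank_distance()]); `method = "ward2"` applies the
#' `"ward.D2"` linkage to the unsquared distances instead.
#'
#' @param d A `dist` of squared Euclidean distances (from [rank_distance()]).
#' @param method `"classical"` or `"ward2"`.
#' @return An `hclust` object (merge heights nondecreasing).
#' @export
ward_cluster <- function(d, method = c("classical", "ward2")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "dist"))
  if (method == "classical") {
    stats::hclust(d, method = "ward.D")
  } else {
    stats::hclust(sqrt(d), method = "ward.D2")
  }
}

#' Cut a dendrogram into k groups
#'
#' @param tree An `hclust` object.
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Tibble with `gen` and integer `cluster`.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k out of range 1..", n, call. = FALSE)
  ct <- stats::cutree(tree, k = k)
  tibble::tibble(gen = names(ct), cluster = unname(ct))
}

#' Export a dendrogram as a Newick string
#'
#' @param tree An `hclust` object.
#' @return Single Newick string (with branch lengths derived from merge
#'   heights), parseable by standard tree readers.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}

#' Cluster genotypes by their stability-index rank profiles
#'
#' Convenience wrapper: extracts the `_R` rank columns of a stability table
#' (see [stability_table()]), computes squared Euclidean distances and runs
#' Ward clustering.
#'
#' @param stats Stability table with rank columns.
#' @param columns Rank columns to use; defaults to every `_R` column present.
#' @param method Linkage variant (see [ward_cluster()]).
#' @return An `hclust` object with genotype labels.
#' @export
cluster_rank_profiles <- function(stats, columns = NULL,
                                  method = c("classical", "ward2")) {
  rank_cols <- grep("_R$", names(stats), value = TRUE)
  if (!is.null(columns)) rank_cols <- intersect(columns, names(stats))
  if (length(rank_cols) == 0) stop("no rank columns found", call. = FALSE)
  p <- as.matrix(stats[rank_cols])
  rownames(p) <- stats$gen
  ward_cluster(rank_distance(p), method = match.arg(method))
}
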