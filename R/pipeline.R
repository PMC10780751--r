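#' Run the full MET stability pipeline
#'
#' Executes every stage on one dataset — joint ANOVA, AMMI decomposition and
#' biplot coordinates, GGE which-won-where and mean-vs-stability, the
#' stability-index table, rank-profile Ward clustering, and trait-yield
#' Spearman correlations — and writes the complete artifact bundle to
#' `out_dir`: `anova.tsv`, `ammi_axes.tsv`, `ammi1_coords.tsv`,
#' `ammi2_coords.tsv`, `gge_coords.tsv`, `www.json`, `mean_stability.tsv`,
#' `stability.tsv`, `cluster_labels.tsv`, `cluster_merges.tsv`,
#' `dendrogram.nwk`, `correlation_rho.tsv`, `correlation_p.tsv` and a
#' `manifest.json` recording the configuration, its hash, the seed and file
#' checksums. Identical input and configuration give bit-identical outputs.
#'
#' @param data Plot-level MET tibble, or `NULL` to simulate one.
#' @param out_dir Output directory (created if missing).
#' @param sim Optional list of arguments for [simulate_met()] when `data` is
#'   `NULL`; the default simulates the package's reference design.
#' @param traits Trait columns to correlate with yield (default: every
#'   numeric non-design column).
#' @param n_axes WAAS axis selection (see [waas()]).
#' @param conf_z Annicchiarico reliability quantile.
#' @param cluster_k Number of rank-profile clusters to cut (default 8).
#' @param seed Seed used when simulating.
#' @return Invisibly, a list with every fitted object and the manifest.
#' @export
run_met_pipeline <- function(data = NULL, out_dir, sim = list(),
                             traits = NULL, n_axes = "significant",
                             conf_z = stats::qnorm(0.75),
                             cluster_k = 8, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(sim = sim, n_axes = n_axes, conf_z = conf_z,
              cluster_k = cluster_k, seed = seed, simulated = is.null(data))
  if (is.null(data)) {
    sim_args <- utils::modifyList(list(seed = seed), sim)
    data <- do.call(simulate_met, sim_args)$data
    data <- simulate_traits(data, seed = seed + 1L)
  }
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    name
  }

  anova_tab <- met_anova(data)
  ammi <- fit_ammi(data)
  gge_www <- fit_gge(data, svp = "symmetric")
  gge_ms <- fit_gge(data, svp = "genotype")
  www <- which_won_where(gge_www)
  ms <- mean_vs_stability(gge_ms)
  st <- stability_table(data, n_axes = n_axes, conf_z = conf_z)
  tree <- cluster_rank_profiles(st)
  labels <- cut_clusters(tree, min(cluster_k, nrow(st)))
  corr <- spearman_matrix(data, traits = traits)

  files <- c(
    tsv(anova_tab, "anova.tsv"),
    tsv(tidy(ammi), "ammi_axes.tsv"),
    tsv(ammi1_coords(ammi), "ammi1_coords.tsv"),
    tsv(ammi2_coords(ammi), "ammi2_coords.tsv"),
    tsv(tidy(gge_www), "gge_coords.tsv"),
    {
      jsonlite::write_json(
        list(hull_vertices = www$hull_vertices,
             sectors = www$sectors, winner_of_sector = www$winner_of_sector),
        file.path(out_dir, "www.json"), auto_unbox = TRUE, digits = NA)
      "www.json"
    },
    tsv(ms, "mean_stability.tsv"),
    tsv(st, "stability.tsv"),
    tsv(labels, "cluster_labels.tsv"),
    tsv(data.frame(node_a = tree$merge[, 1], node_b = tree$merge[, 2],
                   height = tree$height), "cluster_merges.tsv"),
    {
      writeLines(to_newick(tree), file.path(out_dir, "dendrogram.nwk"))
      "dendrogram.nwk"
    },
    tsv(data.frame(trait = rownames(corr$rho), corr$rho, check.names = FALSE),
        "correlation_rho.tsv"),
    tsv(data.frame(trait = rownames(corr$p), corr$p, check.names = FALSE),
        "correlation_p.tsv"))

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "metstab",
    version = as.character(utils::packageVersion("metstab")),
    seed = seed,
    config = cfg,
    config_hash = unname(tools::md5sum(
      {tmp <- tempfile(); writeLines(cfg_json, tmp); tmp})),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = data, anova = anova_tab, ammi = ammi,
                 gge_www = gge_www, gge_ms = gge_ms, www = www,
                 mean_stability = ms, stability = st, tree = tree,
                 clusters = labels, correlation = corr, manifest = manifest))
}
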