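#' Run the full secretome analysis pipeline
#'
#' Executes every stage on a validated dataset: iBAQ conversion,
#' experiment-wide protein grouping, property and rank-percentile
#' computation, secretion classification, biomass accounting (SP/TM
#' category, both location predictors, the secreted predicate, taxonomy at
#' three ranks, COG categories for all and for secreted proteins),
#' secreted-biomass coverage, and the aggregate-candidate screen with
#' complete-linkage clustering.
#'
#' @param dataset A `secretome_dataset` ([read_dataset()] /
#'   [build_dataset()]), or a directory containing `proteins.fasta`,
#'   `quant.tsv`, `annotations.tsv` and `structure.tsv`.
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV with deterministic ordering.
#' @return A list of result tables: `abundance`, `dropped_rows`, `groups`,
#'   `skipped_merges`, `properties`, `ranks`, `secretion`,
#'   `biomass_shares`, `taxonomy_shares`, `cog_shares`, `coverage`,
#'   `candidates`, `clusters`, `linkage`, `cluster_summary`, `heatmap`,
#'   `validation`.
#' @export
run_pipeline <- function(dataset, config = default_config(),
                         out_dir = NULL) {
  if (is.character(dataset)) {
    dataset <- read_dataset(
      fasta = file.path(dataset, "proteins.fasta"),
      quant = file.path(dataset, "quant.tsv"),
      annot = file.path(dataset, "annotations.tsv"),
      struct = file.path(dataset, "structure.tsv"))
  }
  stopifnot(inherits(dataset, "secretome_dataset"))

  proteases <- unlist(config$proteases)
  conv <- ibaq_convert(dataset$quant, dataset$catalogue, proteases,
                       length_range = config$digestion$ibaq_length_range)
  abundance <- conv$abundance

  grouping <- merge_groups(
    distinct(dataset$quant, .data$protein_id, .data$approach,
             .data$approach_group_id))

  props <- property_matrix(dataset, pH = config$charge$pH,
                           pka_table = unlist(config$charge$pka))
  ranks <- rank_matrix(props)
  secretion <- classify_secretion(dataset$annotations)

  category_shares <- biomass_fractions(
    abundance,
    tibble(protein_id = secretion$protein_id, key = secretion$category),
    key_type = "category")
  psortb_shares <- biomass_fractions(
    abundance,
    tibble(protein_id = dataset$annotations$protein_id,
           key = dataset$annotations$psortb_location),
    key_type = "psortb_location")
  deeplocpro_shares <- biomass_fractions(
    abundance,
    tibble(protein_id = dataset$annotations$protein_id,
           key = dataset$annotations$deeplocpro_location),
    key_type = "deeplocpro_location")
  secreted_shares <- biomass_fractions(
    abundance,
    tibble(protein_id = secretion$protein_id,
           key = ifelse(secretion$secreted_or_extracellular,
                        "secreted_or_extracellular", "other")),
    key_type = "secreted")
  biomass_shares <- bind_rows(category_shares, psortb_shares,
                              deeplocpro_shares, secreted_shares)

  taxonomy <- bind_rows(lapply(c("phylum", "class", "genus"), function(r) {
    taxonomy_shares(abundance, dataset$annotations, rank = r)
  }))
  cog_all <- cog_shares(abundance, dataset$annotations, subset = "all") %>%
    mutate(subset = "all")
  cog_sec <- cog_shares(abundance, dataset$annotations, secretion,
                        subset = "secreted_or_extracellular") %>%
    mutate(subset = "secreted_or_extracellular")
  cogs <- bind_rows(cog_all, cog_sec)

  coverage <- coverage_by_approach(abundance, secretion,
                                   thresholds = config$coverage$thresholds)

  candidates <- select_candidates(
    ranks, abundance, secretion,
    rules = default_selection_rules(config$selection$quantile),
    abundance_quantile = config$selection$abundance_quantile)
  clustering <- cluster_candidates(ranks, candidates,
                                   k = config$clustering$k)
  report <- cluster_report(candidates, clustering, abundance, secretion,
                           ranks)

  results <- list(
    abundance = arrange(abundance, .data$protein_id, .data$approach,
                        .data$replicate),
    dropped_rows = conv$dropped,
    groups = grouping$groups,
    skipped_merges = grouping$skipped,
    properties = arrange(props, .data$protein_id),
    ranks = arrange(ranks, .data$protein_id),
    secretion = arrange(secretion, .data$protein_id),
    biomass_shares = biomass_shares,
    taxonomy_shares = taxonomy,
    cog_shares = cogs,
    coverage = coverage,
    candidates = left_join(candidates, clustering$assignments,
                           by = "protein_id"),
    clusters = clustering$assignments,
    linkage = clustering$linkage,
    cluster_summary = report$summary,
    heatmap = report$heatmap,
    validation = dataset$validation
  )

  if (!is.null(out_dir)) {
    write_pipeline_results(results, out_dir)
  }
  results
}

pipeline_output_files <- function() {
  c(abundance = "abundance_ibaq.tsv",
    groups = "groups.tsv",
    skipped_merges = "skipped_merges.tsv",
    properties = "properties.tsv",
    ranks = "ranks.tsv",
    secretion = "secretion_classes.tsv",
    biomass_shares = "biomass_shares.tsv",
    taxonomy_shares = "taxonomy_shares.tsv",
    cog_shares = "cog_shares.tsv",
    coverage = "coverage.tsv",
    candidates = "candidates.tsv",
    linkage = "linkage.tsv",
    cluster_summary = "cluster_summary.tsv",
    heatmap = "cluster_heatmap.tsv",
    validation = "validation_report.tsv")
}

#' Write pipeline result tables as TSV
#'
#' @param results Output of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- pipeline_output_files()
  for (nm in names(files)) {
    readr::write_tsv(results[[nm]], file.path(out_dir, files[[nm]]),
                     progress = FALSE)
  }
  invisible(out_dir)
}
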