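#' Default property-extremeness selection rules
#'
#' High values of GRAVY, beta-sheet fraction, cysteine fraction,
#' aromaticity, protein length and absolute net charge, and low values of
#' surface accessibility and disorder, flag potential aggregate-forming
#' behaviour. Charge is ranked on its absolute value for selection (both
#' strongly positive and strongly negative proteins may cross-link) while
#' the signed percentile is kept for clustering.
#'
#' @param quantile Extremeness quantile (default 0.10).
#' @return Tibble `property`, `direction` (`top`/`bottom`), `quantile`,
#'   `uses_absolute`.
#' @export
default_selection_rules <- function(quantile = 0.10) {
  tibble(
    property = c("gravy", "beta_fraction", "cys_fraction", "aromaticity",
                 "length", "net_charge_abs", "mean_rsa", "mean_disorder"),
    direction = c(rep("top", 6), rep("bottom", 2)),
    quantile = quantile,
    uses_absolute = c(rep(FALSE, 5), TRUE, FALSE, FALSE)
  )
}

#' Select candidate aggregate-forming proteins
#'
#' A protein is selected when all three clauses hold:
#' (i) at least one property percentile is extreme — strictly above
#' `1 - quantile` for a `top` rule, at or below `quantile` for a `bottom`
#' rule; (ii) its abundance is in the top half (percentile strictly above
#' `abundance_quantile`) among the proteins quantified in at least one
#' approach; (iii) it is predicted secreted or extracellular. The ranking
#' universe for clause (i) is every protein with a complete property
#' vector; the universe for clause (ii) is per approach.
#'
#' @param ranks Output of [rank_matrix()].
#' @param abundance iBAQ table ([ibaq_convert()] schema) or pre-averaged
#'   `protein_id`/`approach`/`ibaq` tibble.
#' @param secretion Output of [classify_secretion()].
#' @param rules Selection rules, see [default_selection_rules()].
#' @param abundance_quantile Abundance cutoff (default 0.50).
#' @return Tibble of selected proteins: `protein_id`, one logical
#'   `trig_<property>` column per rule, and `approaches` — the
#'   comma-separated approaches satisfying the abundance clause.
#' @export
select_candidates <- function(ranks, abundance, secretion,
                              rules = default_selection_rules(),
                              abundance_quantile = 0.50) {
  complete <- ranks %>%
    filter(!dplyr::if_any(dplyr::all_of(PROPERTY_NAMES), is.na))
  if (nrow(complete) == 0) abort("empty ranking universe")

  triggers <- tibble(protein_id = complete$protein_id)
  for (i in seq_len(nrow(rules))) {
    p <- rules$property[[i]]
    q <- rules$quantile[[i]]
    pct <- complete[[p]]
    hit <- if (rules$direction[[i]] == "top") pct > 1 - q else pct <= q
    triggers[[paste0("trig_", p)]] <- hit
  }
  trig_cols <- paste0("trig_", rules$property)
  any_trig <- Reduce(`|`, triggers[trig_cols])

  mean_ibaq <- if ("replicate" %in% names(abundance)) {
    approach_mean_ibaq(abundance)
  } else {
    abundance
  }
  abundant <- mean_ibaq %>%
    group_by(.data$approach) %>%
    mutate(pct = rank(.data$ibaq, ties.method = "average") / n()) %>%
    ungroup() %>%
    filter(.data$pct > abundance_quantile) %>%
    group_by(.data$protein_id) %>%
    summarise(approaches = paste(sort(unique(.data$approach)),
                                 collapse = ","),
              .groups = "drop")

  secreted <- secretion$protein_id[secretion$secreted_or_extracellular]

  triggers %>%
    mutate(any_trigger = any_trig) %>%
    filter(.data$any_trigger) %>%
    select(-"any_trigger") %>%
    inner_join(abundant, by = "protein_id") %>%
    filter(.data$protein_id %in% secreted) %>%
    arrange(.data$protein_id)
}

#' Cluster candidates by their property rank profiles
#'
#' Complete-linkage agglomerative clustering on Euclidean distances
#' between the 8 rank-percentile profiles (signed charge percentile), cut
#' into exactly `k` clusters. Cluster ids are relabelled 1..k by
#' decreasing size, ties broken by the smallest member id, so the result
#' is deterministic and independent of candidate input order.
#'
#' @param ranks Output of [rank_matrix()].
#' @param candidates Output of [select_candidates()] (or any tibble with a
#'   `protein_id` column naming the proteins to cluster).
#' @param k Number of clusters (default 9).
#' @return A list: `assignments` (tibble `protein_id`, `cluster_id`),
#'   `tree` (the `hclust` object), `linkage` (tibble `step`, `left`,
#'   `right`, `height`, `size`; negative-free encoding where members are
#'   protein ids and internal nodes are `step_<n>`), and `order` (protein
#'   ids in dendrogram order).
#' @export
cluster_candidates <- function(ranks, candidates, k = 9) {
  ids <- sort(unique(candidates$protein_id))
  if (length(ids) < k) {
    abort(sprintf(
      "fewer candidates (%d) than clusters (k = %d); choose a smaller k",
      length(ids), k))
  }
  feat <- ranks %>%
    filter(.data$protein_id %in% ids) %>%
    arrange(.data$protein_id)
  m <- as.matrix(feat[PROPERTY_NAMES])
  rownames(m) <- feat$protein_id
  tree <- hclust(dist(m, method = "euclidean"), method = "complete")
  raw <- cutree(tree, k = k)

  # relabel clusters by decreasing size, ties by smallest member id
  info <- tibble(protein_id = names(raw), raw = unname(raw)) %>%
    group_by(.data$raw) %>%
    summarise(size = n(), min_id = min(.data$protein_id),
              .groups = "drop") %>%
    arrange(desc(.data$size), .data$min_id) %>%
    mutate(cluster_id = dplyr::row_number())
  assignments <- tibble(protein_id = names(raw), raw = unname(raw)) %>%
    left_join(select(info, "raw", "cluster_id"), by = "raw") %>%
    select("protein_id", "cluster_id") %>%
    arrange(.data$protein_id)

  merge_ <- tree$merge
  sizes <- integer(nrow(merge_))
  node_size <- function(x, step_sizes) {
    if (x < 0) 1L else step_sizes[[x]]
  }
  left <- character(nrow(merge_)); right <- character(nrow(merge_))
  for (s in seq_len(nrow(merge_))) {
    l <- merge_[s, 1]; r <- merge_[s, 2]
    left[[s]] <- if (l < 0) tree$labels[[-l]] else paste0("step_", l)
    right[[s]] <- if (r < 0) tree$labels[[-r]] else paste0("step_", r)
    sizes[[s]] <- node_size(l, sizes) + node_size(r, sizes)
  }
  linkage <- tibble(step = seq_len(nrow(merge_)), left = left,
                    right = right, height = tree$height, size = sizes)

  list(assignments = assignments, tree = tree, linkage = linkage,
       order = tree$labels[tree$order])
}

#' Per-cluster summary report
#'
#' @param candidates Output of [select_candidates()].
#' @param clustering Output of [cluster_candidates()].
#' @param abundance iBAQ table or pre-averaged table.
#' @param secretion Output of [classify_secretion()].
#' @param ranks Output of [rank_matrix()].
#' @return A list: `summary` — per-cluster member count, SP / TM / SP+TM
#'   member counts, mean percentile per property, and the cluster's summed
#'   share of the secreted-or-extracellular biomass per approach (columns
#'   `share_<approach>`) — and `heatmap` — the candidate rank matrix in
#'   dendrogram order with cluster ids, ready for plotting.
#' @export
cluster_report <- function(candidates, clustering, abundance, secretion,
                           ranks) {
  assignments <- clustering$assignments
  mean_ibaq <- if ("replicate" %in% names(abundance)) {
    approach_mean_ibaq(abundance)
  } else {
    abundance
  }
  secreted <- secretion$protein_id[secretion$secreted_or_extracellular]
  sec_tot <- mean_ibaq %>%
    filter(.data$protein_id %in% secreted) %>%
    group_by(.data$approach) %>%
    summarise(total = sum(.data$ibaq), .groups = "drop")
  shares <- mean_ibaq %>%
    inner_join(assignments, by = "protein_id") %>%
    group_by(.data$cluster_id, .data$approach) %>%
    summarise(ibaq = sum(.data$ibaq), .groups = "drop") %>%
    left_join(sec_tot, by = "approach") %>%
    mutate(share = .data$ibaq / .data$total) %>%
    select("cluster_id", "approach", "share") %>%
    tidyr::pivot_wider(names_from = "approach", values_from = "share",
                       names_prefix = "share_", values_fill = 0)

  prop_means <- ranks %>%
    inner_join(assignments, by = "protein_id") %>%
    group_by(.data$cluster_id) %>%
    summarise(across(dplyr::all_of(PROPERTY_NAMES), mean,
                     .names = "mean_{.col}"),
              .groups = "drop")

  comp <- secretion %>%
    inner_join(assignments, by = "protein_id") %>%
    count(.data$cluster_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")

  summary_ <- assignments %>%
    count(.data$cluster_id, name = "n_members") %>%
    left_join(comp, by = "cluster_id") %>%
    left_join(prop_means, by = "cluster_id") %>%
    left_join(shares, by = "cluster_id") %>%
    arrange(.data$cluster_id)

  heatmap <- ranks %>%
    inner_join(assignments, by = "protein_id") %>%
    mutate(protein_id = factor(.data$protein_id,
                               levels = clustering$order)) %>%
    arrange(.data$protein_id) %>%
    mutate(protein_id = as.character(.data$protein_id)) %>%
    select("protein_id", "cluster_id",
           dplyr::all_of(PROPERTY_NAMES))

  list(summary = summary_, heatmap = heatmap)
}

#' Plot the candidate cluster heatmap
#'
#' Renders the dendrogram-ordered rank matrix from [cluster_report()] with
#' `pheatmap`, annotated by cluster id.
#'
#' @param report Output of [cluster_report()].
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_cluster_heatmap <- function(report, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort("pheatmap is required for plotting")
  }
  h <- report$heatmap
  m <- as.matrix(h[PROPERTY_NAMES])
  rownames(m) <- h$protein_id
  ann <- data.frame(cluster = factor(h$cluster_id),
                    row.names = h$protein_id)
  p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                          annotation_row = ann, show_rownames = FALSE,
                          ...)
  invisible(p)
}
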