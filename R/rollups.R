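#' Convert intensities to iBAQ
#'
#' Divides each quantification row's intensity by the theoretical number of
#' fully specific, zero-missed-cleavage peptides of the row's protein under
#' the protease regime of its approach (and, where digestion differed
#' between replicates, of its (approach, replicate) pair). Rows whose
#' theoretical peptide count is zero cannot be converted; they are dropped
#' and reported.
#'
#' @param quant Quantification tibble ([read_quant()] schema).
#' @param catalogue Catalogue tibble with `protein_id`, `sequence`.
#' @param protease_by_approach Either a named character vector mapping
#'   approach to protease, or a tibble with columns `approach`,
#'   `replicate`, `protease` for per-replicate regimes.
#' @param length_range Peptide length window for the theoretical count,
#'   default `c(7, 30)`.
#' @return A list with `abundance` — the quant rows plus `protease`,
#'   `theoretical_peptides` and `ibaq` columns — and `dropped` — rows
#'   removed because no theoretical peptide exists.
#' @export
ibaq_convert <- function(quant, catalogue, protease_by_approach,
                         length_range = c(7, 30)) {
  missing_ids <- setdiff(unique(quant$protein_id), catalogue$protein_id)
  if (length(missing_ids) > 0) {
    abort(paste0("protein absent from catalogue: ", missing_ids[[1]]))
  }
  if (is.data.frame(protease_by_approach)) {
    q <- quant %>%
      left_join(protease_by_approach, by = c("approach", "replicate"))
  } else {
    q <- quant %>%
      mutate(protease = unname(protease_by_approach[.data$approach]))
  }
  if (any(is.na(q$protease))) {
    abort(paste0("no protease regime for approach ",
                 q$approach[is.na(q$protease)][[1]]))
  }
  counts <- q %>%
    distinct(.data$protein_id, .data$protease) %>%
    left_join(catalogue, by = "protein_id") %>%
    rowwise() %>%
    mutate(theoretical_peptides = theoretical_peptide_count(
      .data$sequence, .data$protease, length_range)) %>%
    ungroup() %>%
    select("protein_id", "protease", "theoretical_peptides")
  q <- q %>% left_join(counts, by = c("protein_id", "protease"))
  dropped <- q %>% filter(.data$theoretical_peptides == 0)
  if (nrow(dropped) > 0) {
    inform(paste0(nrow(dropped), " quant row(s) dropped: no theoretical ",
                  "peptide for their protease regime"))
  }
  abundance <- q %>%
    filter(.data$theoretical_peptides > 0) %>%
    mutate(ibaq = .data$intensity / .data$theoretical_peptides)
  list(abundance = abundance, dropped = dropped)
}

#' Biomass shares by taxonomic rank
#'
#' @param abundance iBAQ table ([ibaq_convert()] schema) or pre-averaged
#'   `protein_id`/`approach`/`ibaq` table.
#' @param annotations Annotation tibble with `phylum`, `class`, `genus`.
#' @param rank One of `"phylum"`, `"class"`, `"genus"`.
#' @return Tibble `approach`, `key_type`, `key` (taxon, `unclassified`
#'   kept as its own key), `share`; shares sum to 1 per approach.
#' @export
taxonomy_shares <- function(abundance, annotations,
                            rank = c("phylum", "class", "genus")) {
  rank <- match.arg(rank)
  labels <- tibble(protein_id = annotations$protein_id,
                   key = annotations[[rank]])
  biomass_fractions(abundance, labels, key_type = rank)
}

#' Biomass shares by COG category
#'
#' A protein annotated with several COG categories contributes its full
#' iBAQ to each of them (no splitting), so shares may sum to more than 1.
#' Proteins without a COG annotation are reported under `"NA"`; category
#' `S` (function unknown) is kept distinct from `"NA"`. Categories below
#' `other_floor` can be merged into `"Other"` in report output via
#' [collapse_minor_categories()]; shares returned here are exact.
#'
#' @param abundance iBAQ table or pre-averaged table (see
#'   [taxonomy_shares()]).
#' @param annotations Annotation tibble with a `cog` column of
#'   single-letter category strings.
#' @param secretion Optional [classify_secretion()] output; required when
#'   `subset = "secreted_or_extracellular"`.
#' @param subset `"all"` or `"secreted_or_extracellular"` (denominator and
#'   numerator restricted to the secreted-or-extracellular proteins).
#' @return Tibble `approach`, `key_type` (`"cog"`), `key`, `share`.
#' @export
cog_shares <- function(abundance, annotations, secretion = NULL,
                       subset = c("all", "secreted_or_extracellular")) {
  subset <- match.arg(subset)
  mean_ibaq <- if ("replicate" %in% names(abundance)) {
    approach_mean_ibaq(abundance)
  } else {
    abundance
  }
  if (subset == "secreted_or_extracellular") {
    if (is.null(secretion)) {
      abort("secretion classes required for the secreted subset")
    }
    keep <- secretion$protein_id[secretion$secreted_or_extracellular]
    mean_ibaq <- mean_ibaq %>% filter(.data$protein_id %in% keep)
  }
  totals <- mean_ibaq %>%
    group_by(.data$approach) %>%
    summarise(total = sum(.data$ibaq), .groups = "drop")
  cats <- strsplit(annotations$cog, "")
  cats[annotations$cog == ""] <- list("NA")  # no-COG sentinel key
  cogs <- tibble(protein_id = annotations$protein_id, category = cats) %>%
    tidyr::unnest("category") %>%
    distinct(.data$protein_id, .data$category)
  mean_ibaq %>%
    inner_join(cogs, by = "protein_id",
               relationship = "many-to-many") %>%
    group_by(.data$approach, .data$category) %>%
    summarise(ibaq = sum(.data$ibaq), .groups = "drop") %>%
    left_join(totals, by = "approach") %>%
    transmute(.data$approach, key_type = "cog", key = .data$category,
              share = .data$ibaq / .data$total) %>%
    arrange(.data$approach, desc(.data$share), .data$key)
}

#' Merge minor categories into "Other" for reporting
#'
#' @param shares Output of [cog_shares()] or [biomass_fractions()].
#' @param floor Minimum share retained as its own key (default 0.02).
#' @return Same schema, with sub-floor keys pooled into `"Other"`.
#' @export
collapse_minor_categories <- function(shares, floor = 0.02) {
  shares %>%
    mutate(key = ifelse(.data$share < floor, "Other", .data$key)) %>%
    group_by(.data$approach, .data$key_type, .data$key) %>%
    summarise(share = sum(.data$share), .groups = "drop") %>%
    arrange(.data$approach, desc(.data$share), .data$key)
}
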