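#' Classify proteins by secretion evidence
#'
#' Assigns each protein to one of four categories from its signal-peptide
#' call and transmembrane-domain count — `SP` (signal peptide only), `TM`
#' (transmembrane domains only), `SP+TM` (both), `None` (neither) — and
#' evaluates the secreted-or-extracellular predicate: a predicted signal
#' peptide, or an `extracellular` call from either location predictor.
#'
#' @param annotations Annotation tibble ([read_annotations()] schema).
#' @return Tibble `protein_id`, `category`, `secreted_or_extracellular`.
#' @export
classify_secretion <- function(annotations) {
  tm <- annotations$tm_count > 0
  sp <- annotations$signal_peptide
  tibble(
    protein_id = annotations$protein_id,
    category = case_when(sp & tm ~ "SP+TM",
                         sp ~ "SP",
                         tm ~ "TM",
                         TRUE ~ "None"),
    secreted_or_extracellular =
      sp | annotations$psortb_location == "extracellular" |
      annotations$deeplocpro_location == "extracellular"
  )
}

#' Average iBAQ over replicates within each approach
#'
#' Proteins missing from a replicate contribute 0 to the mean, i.e. the
#' per-approach value is the row sum divided by the number of replicates
#' observed for that approach.
#'
#' @param abundance iBAQ table with `protein_id`, `approach`, `replicate`,
#'   `ibaq` (see [ibaq_convert()]).
#' @return Tibble `protein_id`, `approach`, `ibaq`.
#' @export
approach_mean_ibaq <- function(abundance) {
  n_rep <- abundance %>%
    group_by(.data$approach) %>%
    summarise(n_rep = length(unique(.data$replicate)), .groups = "drop")
  abundance %>%
    group_by(.data$protein_id, .data$approach) %>%
    summarise(total = sum(.data$ibaq), .groups = "drop") %>%
    left_join(n_rep, by = "approach") %>%
    mutate(ibaq = .data$total / .data$n_rep) %>%
    select("protein_id", "approach", "ibaq")
}

#' Biomass fractions by an arbitrary grouping key
#'
#' For each approach, the share of a key is the summed mean iBAQ of the
#' proteins carrying that key divided by the total mean iBAQ of the
#' approach. Shares over a partition of the proteins sum to 1.
#'
#' @param abundance Per-replicate iBAQ table ([ibaq_convert()] schema) or a
#'   pre-averaged table with columns `protein_id`, `approach`, `ibaq`.
#' @param labels Tibble `protein_id`, `key` assigning each protein one key.
#' @param key_type Label stored in the output's `key_type` column.
#' @return Tibble `approach`, `key_type`, `key`, `share`.
#' @export
biomass_fractions <- function(abundance, labels, key_type = "key") {
  mean_ibaq <- if ("replicate" %in% names(abundance)) {
    approach_mean_ibaq(abundance)
  } else {
    abundance
  }
  joined <- mean_ibaq %>%
    inner_join(labels, by = "protein_id")
  totals <- joined %>%
    group_by(.data$approach) %>%
    summarise(total = sum(.data$ibaq), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("approach with zero total abundance: ",
                 totals$approach[totals$total <= 0][[1]]))
  }
  joined %>%
    group_by(.data$approach, .data$key) %>%
    summarise(ibaq = sum(.data$ibaq), .groups = "drop") %>%
    left_join(totals, by = "approach") %>%
    transmute(.data$approach, key_type = key_type, .data$key,
              share = .data$ibaq / .data$total) %>%
    arrange(.data$approach, desc(.data$share), .data$key)
}

#' Minimal protein counts covering secreted biomass thresholds
#'
#' For each threshold `t`, the smallest number of proteins whose largest
#' abundances sum to at least `t` of the total. Ties between equal
#' abundances are broken by protein id, so the result is deterministic.
#'
#' @param abundance Tibble `protein_id`, `ibaq` (one approach, already
#'   restricted to the secreted proteins of interest).
#' @param thresholds Numeric vector of fractions in (0, 1\].
#' @return Tibble `threshold`, `n_proteins`.
#' @export
#' @examples
#' x <- tibble::tibble(protein_id = c("a", "b", "c"),
#'                     ibaq = c(0.5, 0.3, 0.2))
#' cumulative_coverage(x, c(0.5, 0.75))
cumulative_coverage <- function(abundance, thresholds = c(0.5, 0.75)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must lie in (0, 1]")
  }
  pos <- abundance %>% filter(.data$ibaq > 0)
  if (nrow(pos) == 0) {
    abort("no secreted protein with positive abundance")
  }
  ordered <- pos %>%
    arrange(desc(.data$ibaq), .data$protein_id)
  cum <- cumsum(ordered$ibaq) / sum(ordered$ibaq)
  tibble(
    threshold = thresholds,
    n_proteins = vapply(thresholds,
                        function(t) which(cum >= t - 1e-12)[[1]],
                        0L)
  )
}

#' Secreted-biomass coverage per approach
#'
#' Convenience wrapper: restricts the abundance table to
#' secreted-or-extracellular proteins and computes
#' [cumulative_coverage()] per approach.
#'
#' @param abundance iBAQ table ([ibaq_convert()] schema).
#' @param secretion Output of [classify_secretion()].
#' @param thresholds Fractions in (0, 1].
#' @return Tibble `approach`, `threshold`, `n_proteins`.
#' @export
coverage_by_approach <- function(abundance, secretion,
                                 thresholds = c(0.5, 0.75)) {
  secreted <- secretion$protein_id[secretion$secreted_or_extracellular]
  mean_ibaq <- approach_mean_ibaq(abundance) %>%
    filter(.data$protein_id %in% secreted)
  mean_ibaq %>%
    group_by(.data$approach) %>%
    group_modify(~ cumulative_coverage(.x, thresholds)) %>%
    ungroup()
}
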