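#' Merge approach-specific protein groups into experiment-wide groups
#'
#' Two proteins end up in the same experiment-wide group when they share an
#' approach-specific protein group in at least one approach (directly or
#' transitively) and are never assigned to different approach-specific
#' groups within any single approach. Group ids are scoped per approach:
#' the same string in two approaches does not link proteins.
#'
#' The pairwise rule can be transitively inconsistent (approach A links
#' p1-p2, B links p2-p3, C separates p1 and p3). Candidate merges are
#' therefore processed in canonical order — approach name, then group id,
#' then protein id, all lexicographic — and a merge that would place
#' conflicting proteins into one group is skipped and logged, making the
#' rule total and deterministic regardless of input row order.
#'
#' @param assignments Tibble with columns `protein_id`, `approach`,
#'   `approach_group_id`, one row per (protein, approach) membership.
#'   Proteins absent from an approach simply have no row for it.
#' @return A list with `groups` — tibble `protein_id`,
#'   `experiment_group_id` (the lexicographically smallest member id
#'   prefixed `"EG_"`) — and `skipped` — tibble of merges skipped due to
#'   cross-approach conflicts (`approach`, `approach_group_id`,
#'   `protein_a`, `protein_b`).
#' @export
#' @examples
#' x <- tibble::tribble(
#'   ~protein_id, ~approach, ~approach_group_id,
#'   "p1", "whole", "g1",
#'   "p2", "whole", "g1",
#'   "p2", "shaved", "h1",
#'   "p3", "shaved", "h1")
#' merge_groups(x)$groups
merge_groups <- function(assignments) {
  stopifnot(all(c("protein_id", "approach", "approach_group_id") %in%
                  names(assignments)))
  assignments <- distinct(assignments, .data$protein_id, .data$approach,
                          .data$approach_group_id)
  dup <- assignments %>%
    count(.data$protein_id, .data$approach) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("protein %s carries two group ids in approach %s",
                  dup$protein_id[[1]], dup$approach[[1]]))
  }

  ids <- sort(unique(assignments$protein_id))
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  # per-approach group id of each protein (NA = unconstrained)
  approaches <- sort(unique(assignments$approach))
  gid <- lapply(approaches, function(a) {
    rows <- assignments[assignments$approach == a, ]
    out <- rep(NA_character_, n)
    out[idx[rows$protein_id]] <- rows$approach_group_id
    out
  })
  names(gid) <- approaches
  # component -> approach -> group id (components are conflict-free, so at
  # most one id per approach per component)
  comp_gid <- lapply(seq_len(n), function(i) {
    vapply(gid, function(g) g[[i]], "")
  })

  conflicts <- function(ra, rb) {
    ga <- comp_gid[[ra]]; gb <- comp_gid[[rb]]
    both <- !is.na(ga) & !is.na(gb)
    any(ga[both] != gb[both])
  }

  skipped <- list()
  ordered <- assignments %>%
    arrange(.data$approach, .data$approach_group_id, .data$protein_id)
  key <- paste(ordered$approach, ordered$approach_group_id)
  for (grp in split(seq_len(nrow(ordered)), factor(key, unique(key)))) {
    members <- ordered$protein_id[grp]
    if (length(members) < 2) next
    anchor <- members[[1]]
    for (m in members[-1]) {
      ra <- find(idx[[anchor]]); rb <- find(idx[[m]])
      if (ra == rb) next
      if (conflicts(ra, rb)) {
        skipped[[length(skipped) + 1]] <- tibble(
          approach = ordered$approach[grp[[1]]],
          approach_group_id = ordered$approach_group_id[grp[[1]]],
          protein_a = anchor, protein_b = m)
        next
      }
      merged <- comp_gid[[ra]]
      take <- is.na(merged)
      merged[take] <- comp_gid[[rb]][take]
      parent[[rb]] <- ra
      comp_gid[[ra]] <- merged
    }
  }

  root <- vapply(seq_len(n), find, 0L)
  groups <- tibble(protein_id = ids, root = root) %>%
    group_by(.data$root) %>%
    mutate(experiment_group_id = paste0("EG_", min(.data$protein_id))) %>%
    ungroup() %>%
    select(-"root") %>%
    arrange(.data$protein_id)

  skipped <- if (length(skipped) > 0) bind_rows(skipped) else
    tibble(approach = character(), approach_group_id = character(),
           protein_a = character(), protein_b = character())
  list(groups = groups, skipped = skipped)
}
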