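# Independent oracles, written against the definitions rather than the
# package implementation, for cross-checking the fast paths.

# protease rules restated independently: named list of cut-after residues
# and residues that suppress cleavage when following the cut site
oracle_rules <- list(
  trypsin = list(after = c("K", "R"), block = "P"),
  chymotrypsin = list(after = c("F", "W", "Y"), block = "P"),
  lysc = list(after = "K", block = character())
)

# is position p (0-based boundary, 1..len-1) a cleavage site?
oracle_is_site <- function(chars, p, protease) {
  if (protease == "lysc_trypsin") {
    return(oracle_is_site(chars, p, "lysc") ||
             oracle_is_site(chars, p, "trypsin"))
  }
  r <- oracle_rules[[protease]]
  chars[p] %in% r$after && !(chars[p + 1] %in% r$block)
}

oracle_sites <- function(sequence, protease) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  Filter(function(p) oracle_is_site(chars, p, protease), seq_len(n - 1))
}

# brute force: enumerate every substring, apply the terminus and
# missed-cleavage predicates directly to each candidate
brute_digest <- function(sequence, protease, max_missed, mode,
                         length_range) {
  n <- nchar(sequence)
  sites <- unlist(oracle_sites(sequence, protease))
  bounds <- c(0L, sites, n)
  grid <- expand.grid(start = 0:(n - 1), end = 1:n)
  grid <- grid[grid$end > grid$start, , drop = FALSE]
  len <- grid$end - grid$start
  grid <- grid[len >= length_range[[1]] & len <= length_range[[2]], ,
               drop = FALSE]
  if (length(sites) > 0) {
    spanned <- rowSums(outer(grid$start, sites, `<`) &
                         outer(grid$end, sites, `>`))
  } else {
    spanned <- rep(0, nrow(grid))
  }
  grid <- grid[spanned <= max_missed, , drop = FALSE]
  n_enz <- grid$start %in% bounds
  c_enz <- grid$end %in% bounds
  ok <- if (mode == "specific") n_enz & c_enz else n_enz | c_enz
  df <- grid[ok, , drop = FALSE]
  df[order(df$start, df$end), , drop = FALSE]
}

expect_same_peptides <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(as.integer(got$start), as.integer(want$start))
  expect_equal(as.integer(got$end), as.integer(want$end))
}

random_aa_sequence <- function(len, with_x = FALSE) {
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                if (with_x) "X")
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# canonical-order greedy grouping on explicit sets of proteins, kept
# structurally different from the package's union-find path
oracle_merge_groups <- function(assignments) {
  assignments <- unique(assignments[c("protein_id", "approach",
                                      "approach_group_id")])
  ids <- sort(unique(assignments$protein_id))
  comps <- as.list(ids)
  gid_of <- function(protein, approach) {
    hit <- assignments$approach == approach &
      assignments$protein_id == protein
    if (!any(hit)) NA_character_ else assignments$approach_group_id[hit]
  }
  approaches <- sort(unique(assignments$approach))
  comp_conflicts <- function(members) {
    for (a in approaches) {
      gids <- stats::na.omit(vapply(members, gid_of, "", approach = a))
      if (length(unique(gids)) > 1) return(TRUE)
    }
    FALSE
  }
  ord <- assignments[order(assignments$approach,
                           assignments$approach_group_id,
                           assignments$protein_id), ]
  keys <- unique(paste(ord$approach, ord$approach_group_id, sep = "\r"))
  for (k in keys) {
    parts <- strsplit(k, "\r")[[1]]
    members <- sort(ord$protein_id[ord$approach == parts[[1]] &
                                     ord$approach_group_id == parts[[2]]])
    if (length(members) < 2) next
    anchor <- members[[1]]
    for (m in members[-1]) {
      ia <- which(vapply(comps, function(s) anchor %in% s, TRUE))
      ib <- which(vapply(comps, function(s) m %in% s, TRUE))
      if (ia == ib) next
      merged <- union(comps[[ia]], comps[[ib]])
      if (comp_conflicts(merged)) next
      comps[[ia]] <- merged
      comps <- comps[-ib]
    }
  }
  out <- do.call(rbind, lapply(comps, function(s) {
    data.frame(protein_id = sort(s),
               experiment_group_id = paste0("EG_", min(s)))
  }))
  out[order(out$protein_id), , drop = FALSE]
}

random_grouping_instance <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  ids <- sprintf("p%02d", seq_len(n))
  rows <- list()
  for (a in c("shaved", "supernatant", "whole")) {
    present <- ids[stats::runif(n) < 0.7]
    if (length(present) == 0) next
    gid <- paste0("g", sample.int(max(1, length(present) - 1),
                                  length(present), replace = TRUE))
    rows[[a]] <- data.frame(protein_id = present, approach = a,
                            approach_group_id = gid)
  }
  do.call(rbind, rows)
}

# per-residue loops for the sequence property calculators
oracle_gravy <- function(sequence) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  total <- 0; k <- 0
  for (ch in strsplit(sequence, "")[[1]]) {
    if (ch %in% names(kd)) {
      total <- total + kd[[ch]]
      k <- k + 1
    }
  }
  total / k
}

oracle_fraction <- function(sequence, residues) {
  k <- 0
  chars <- strsplit(sequence, "")[[1]]
  for (ch in chars) if (ch %in% residues) k <- k + 1
  k / length(chars)
}
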