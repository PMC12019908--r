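#' Cleavage rule definitions
#'
#' Expasy-style rules for the four protease regimes used in granule shaving
#' and bulk digestion. Trypsin cuts after K/R unless the next residue is P;
#' chymotrypsin (high specificity) after F/W/Y unless the next residue is P;
#' LysC after K regardless of a following proline; LysC/trypsin is the site
#' union of LysC and trypsin.
#'
#' @param protease One of `"trypsin"`, `"chymotrypsin"`, `"lysc"`,
#'   `"lysc_trypsin"`.
#' @return A list with elements `protease`, `cut_after` (character vector)
#'   and `suppressed_before` (character vector, possibly empty).
#' @export
cleavage_rule <- function(protease) {
  switch(protease,
    trypsin = list(protease = "trypsin",
                   cut_after = c("K", "R"), suppressed_before = "P"),
    chymotrypsin = list(protease = "chymotrypsin",
                        cut_after = c("F", "W", "Y"),
                        suppressed_before = "P"),
    lysc = list(protease = "lysc",
                cut_after = "K", suppressed_before = character()),
    lysc_trypsin = list(protease = "lysc_trypsin",
                        cut_after = NULL, suppressed_before = NULL),
    abort(paste0("unknown protease: ", protease))
  )
}

#' Enumerate cleavage sites
#'
#' A site is the 0-based position of the backbone bond that is cut, i.e. the
#' boundary index in half-open coordinates: site `p` separates residues
#' `[0, p)` from `[p, len)`. Protein termini (0 and `len`) are never listed.
#'
#' @param sequence Amino-acid sequence (uppercase).
#' @param protease Protease regime, see [cleavage_rule()].
#' @return Strictly increasing integer vector of cut positions in
#'   `[1, len - 1]`.
#' @export
#' @examples
#' cleavage_sites("MKRPLAK", "trypsin") # K2 cuts, R3 blocked by P, K7 terminal
cleavage_sites <- function(sequence, protease) {
  stopifnot(nchar(sequence) >= 1)
  if (protease == "lysc_trypsin") {
    return(sort(union(cleavage_sites(sequence, "lysc"),
                      cleavage_sites(sequence, "trypsin"))))
  }
  rule <- cleavage_rule(protease)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  pos <- seq_len(n - 1)
  hit <- chars[pos] %in% rule$cut_after
  if (length(rule$suppressed_before) > 0) {
    hit <- hit & !(chars[pos + 1] %in% rule$suppressed_before)
  }
  pos[hit]
}

#' In-silico digestion
#'
#' Generates the peptide population of a protease digest. In `specific`
#' mode every peptide is bounded by cut sites or protein termini; in
#' `semispecific` mode peptides with exactly one enzymatic terminus (the
#' other end anywhere in the chain) are additionally emitted, as produced
#' by limited proteolysis of folded substrates. `n_missed` counts the
#' internal cleavage sites a peptide spans and is limited by `max_missed`
#' in both modes.
#'
#' @param sequence Amino-acid sequence.
#' @param protease Protease regime, see [cleavage_rule()].
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param mode `"specific"` or `"semispecific"`.
#' @param length_range Length window `c(min, max)` in residues,
#'   default `c(7, 30)`.
#' @return Tibble with columns `start`, `end` (0-based half-open),
#'   `sequence`, `n_missed`, `specificity` (`full`, `semi_n`, `semi_c`),
#'   ordered by `start` then `end`. No two rows share (start, end).
#' @export
digest <- function(sequence, protease, max_missed = 0,
                   mode = c("specific", "semispecific"),
                   length_range = c(7, 30)) {
  mode <- match.arg(mode)
  stopifnot(max_missed >= 0, length_range[[1]] >= 1)
  if (length_range[[1]] > length_range[[2]]) {
    abort("length_range min exceeds max")
  }
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, protease)
  bounds <- c(0L, sites, n)

  # fully specific peptides: all ordered boundary pairs within limits
  nb <- length(bounds)
  starts <- integer(0); ends <- integer(0)
  for (a in seq_len(nb - 1)) {
    b_max <- min(nb, a + 1 + max_missed)
    bs <- seq(a + 1, b_max)
    starts <- c(starts, rep(bounds[[a]], length(bs)))
    ends <- c(ends, bounds[bs])
  }
  full <- tibble(start = starts, end = ends)

  if (mode == "semispecific") {
    # one terminus on a boundary, the other anywhere
    all_pos <- 0:n
    semi_n <- tidyr::expand_grid(start = bounds[-nb], end = all_pos) %>%
      filter(.data$end > .data$start)
    semi_c <- tidyr::expand_grid(start = all_pos, end = bounds[-1]) %>%
      filter(.data$end > .data$start)
    cand <- bind_rows(full, semi_n, semi_c) %>%
      distinct(.data$start, .data$end)
  } else {
    cand <- distinct(full, .data$start, .data$end)
  }

  len <- cand$end - cand$start
  nm <- count_spanned(cand$start, cand$end, sites)
  keep <- len >= length_range[[1]] & len <= length_range[[2]] &
    nm <= max_missed
  cand <- cand[keep, , drop = FALSE]
  nm <- nm[keep]
  if (nrow(cand) == 0) {
    return(tibble(start = integer(), end = integer(),
                  sequence = character(), n_missed = integer(),
                  specificity = character()))
  }

  n_term_enz <- cand$start %in% bounds
  c_term_enz <- cand$end %in% bounds
  spec <- ifelse(n_term_enz & c_term_enz, "full",
                 ifelse(n_term_enz, "semi_n", "semi_c"))

  out <- tibble(
    start = as.integer(cand$start),
    end = as.integer(cand$end),
    sequence = substring(sequence, cand$start + 1, cand$end),
    n_missed = as.integer(nm),
    specificity = spec
  ) %>% arrange(.data$start, .data$end)
  out
}

# number of cleavage sites strictly inside (start, end), vectorized
count_spanned <- function(start, end, sites) {
  if (length(sites) == 0) return(rep(0L, length(start)))
  findInterval(end - 0.5, sites) - findInterval(start + 0.5, sites)
}

#' Theoretical peptide count for iBAQ
#'
#' The number of fully specific, zero-missed-cleavage peptides whose length
#' falls inside `length_range` — the denominator used to convert summed
#' intensities to iBAQ values.
#'
#' @inheritParams digest
#' @return Non-negative integer.
#' @export
#' @examples
#' theoretical_peptide_count("MKAAAAAAKLLLLLLLR", "trypsin") # 2
theoretical_peptide_count <- function(sequence, protease,
                                      length_range = c(7, 30)) {
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_sites(sequence, protease), n)
  seg <- diff(bounds)
  sum(seg >= length_range[[1]] & seg <= length_range[[2]])
}

#' Theoretical peptide counts for a catalogue
#'
#' Vectorized, memoised wrapper of [theoretical_peptide_count()].
#'
#' @param sequences Named character vector (names = protein ids) or a
#'   catalogue tibble with `protein_id` and `sequence`.
#' @inheritParams digest
#' @return Tibble with `protein_id`, `protease`, `theoretical_peptides`.
#' @export
theoretical_peptide_counts <- function(sequences, protease,
                                       length_range = c(7, 30)) {
  if (is.data.frame(sequences)) {
    ids <- sequences$protein_id
    seqs <- sequences$sequence
  } else {
    ids <- names(sequences)
    seqs <- unname(sequences)
  }
  tibble(
    protein_id = ids,
    protease = protease,
    theoretical_peptides = vapply(
      seqs, theoretical_peptide_count, 0L,
      protease = protease, length_range = length_range,
      USE.NAMES = FALSE)
  )
}

#' Write a peptide table as TSV
#'
#' Emits 1-based inclusive coordinates (`start_1based`, `end_1based`)
#' alongside the peptide sequence; internal coordinates are 0-based
#' half-open.
#'
#' @param peptides Output of [digest()] plus a `protein_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  out <- peptides %>%
    transmute(.data$protein_id,
              start_1based = .data$start + 1L,
              end_1based = .data$end,
              .data$sequence, .data$n_missed, .data$specificity)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
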