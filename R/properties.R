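#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' EMBOSS pKa table for net-charge calculation
#'
#' Terminal groups are keyed `Nterm` and `Cterm`.
#'
#' @return Named numeric vector of pKa values.
#' @export
emboss_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over residues that carry a scale value;
#' the ambiguity code X is excluded from both numerator and denominator.
#'
#' @param sequence Amino-acid sequence.
#' @return Numeric scalar.
#' @export
#' @examples
#' gravy("IK") # (4.5 - 3.9) / 2
gravy <- function(sequence) {
  scale <- kyte_doolittle()
  v <- scale[seq_chars(sequence)]
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("no scorable residues")
  mean(v)
}

#' Aromaticity
#'
#' Fraction of F, W and Y residues; the denominator is the full sequence
#' length (X included).
#'
#' @param sequence Amino-acid sequence.
#' @return Numeric in \[0, 1\].
#' @export
aromaticity <- function(sequence) {
  if (nchar(sequence) == 0) abort("empty sequence")
  mean(seq_chars(sequence) %in% c("F", "W", "Y"))
}

#' Cysteine fraction
#'
#' Fraction of C residues over the full sequence length.
#'
#' @param sequence Amino-acid sequence.
#' @return Numeric in \[0, 1\].
#' @export
cys_fraction <- function(sequence) {
  if (nchar(sequence) == 0) abort("empty sequence")
  mean(seq_chars(sequence) == "C")
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains plus one N-terminal
#' and one C-terminal group: basic groups (N-terminus, K, R, H) contribute
#' `+1 / (1 + 10^(pH - pKa))`, acidic groups (C-terminus, D, E, C, Y)
#' contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param sequence Amino-acid sequence.
#' @param pH Solution pH, in (0, 14). Default 7.0.
#' @param pka_table Named pKa vector, see [emboss_pka()].
#' @return Numeric scalar (elementary charges).
#' @export
#' @examples
#' net_charge("GG") # terminal groups only, ~ -0.024 at pH 7
net_charge <- function(sequence, pH = 7.0, pka_table = emboss_pka()) {
  stopifnot(pH > 0, pH < 14, nchar(sequence) >= 1)
  chars <- seq_chars(sequence)
  basic_res <- c("K", "R", "H")
  acidic_res <- c("C", "D", "E", "Y")
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) 1 / (1 + 10^(pka - pH))
  charge <- pos_frac(pka_table[["Nterm"]]) - neg_frac(pka_table[["Cterm"]])
  for (res in basic_res) {
    k <- sum(chars == res)
    if (k > 0) charge <- charge + k * pos_frac(pka_table[[res]])
  }
  for (res in acidic_res) {
    k <- sum(chars == res)
    if (k > 0) charge <- charge - k * neg_frac(pka_table[[res]])
  }
  charge
}

#' Aggregate per-residue structure predictions per protein
#'
#' @param structure Long tibble in the [read_structure()] schema.
#' @return Tibble with `protein_id`, `beta_fraction` (fraction of residues
#'   in class E), `mean_rsa`, `mean_disorder`.
#' @export
structure_aggregates <- function(structure) {
  structure %>%
    group_by(.data$protein_id) %>%
    summarise(beta_fraction = mean(.data$ss_class == "E"),
              mean_rsa = mean(.data$rsa),
              mean_disorder = mean(.data$disorder),
              .groups = "drop")
}

#' Average-rank percentiles
#'
#' Ascending ranks with ties averaged, scaled by the number of values, so
#' percentiles lie in (0, 1] and tied values share identical percentiles.
#'
#' @param values Numeric vector (length >= 2, all finite).
#' @param ids Optional names used in error messages.
#' @return Numeric vector of percentiles, same order as `values`.
#' @export
#' @examples
#' rank_percentiles(c(5, 5, 10)) # 0.5, 0.5, 1
rank_percentiles <- function(values, ids = NULL) {
  if (length(values) < 2) abort("need at least 2 values to rank")
  bad <- !is.finite(values)
  if (any(bad)) {
    who <- if (!is.null(ids)) ids[bad][[1]] else which(bad)[[1]]
    abort(paste0("non-finite value for ", who))
  }
  rank(values, ties.method = "average") / length(values)
}

#' Compute the per-protein property matrix
#'
#' Five sequence-based properties (GRAVY, aromaticity, net charge, cysteine
#' fraction, length) for every catalogue protein, joined with the three
#' structural aggregates (beta-sheet fraction, mean relative surface
#' accessibility, mean disorder) where a structure table is available.
#' Proteins without structure rows carry `NA` in the structural columns and
#' are excluded from the rankings of those properties only.
#'
#' @param dataset A `secretome_dataset` (see [read_dataset()]), or a list
#'   with at least `catalogue` and `structure`.
#' @param pH pH for the net-charge model (default 7.0).
#' @param pka_table pKa set (default [emboss_pka()]).
#' @return Tibble `protein_id` + the 8 property columns.
#' @export
property_matrix <- function(dataset, pH = 7.0, pka_table = emboss_pka()) {
  cat_ <- dataset$catalogue
  seqs <- cat_$sequence
  props <- tibble(
    protein_id = cat_$protein_id,
    gravy = vapply(seqs, gravy, 0, USE.NAMES = FALSE),
    aromaticity = vapply(seqs, aromaticity, 0, USE.NAMES = FALSE),
    net_charge = vapply(seqs, net_charge, 0, pH = pH,
                        pka_table = pka_table, USE.NAMES = FALSE),
    cys_fraction = vapply(seqs, cys_fraction, 0, USE.NAMES = FALSE),
    length = nchar(seqs)
  )
  agg <- structure_aggregates(dataset$structure)
  left_join(props, agg, by = "protein_id")
}

#' Rank-percentile matrix for screening and clustering
#'
#' Converts each property column of [property_matrix()] output to
#' average-rank percentiles over the proteins measured for that property.
#' Net charge appears twice: `net_charge` (signed, used for clustering) and
#' `net_charge_abs` (percentile of the absolute value, used for the
#' selection rule, since both strongly positive and strongly negative
#' proteins may aggregate).
#'
#' @param properties Output of [property_matrix()].
#' @return Tibble `protein_id` + 9 percentile columns.
#' @export
rank_matrix <- function(properties) {
  out <- tibble(protein_id = properties$protein_id)
  for (p in PROPERTY_NAMES) {
    v <- properties[[p]]
    ok <- !is.na(v)
    col <- rep(NA_real_, length(v))
    col[ok] <- rank_percentiles(v[ok], ids = properties$protein_id[ok])
    out[[p]] <- col
  }
  av <- abs(properties$net_charge)
  ok <- !is.na(av)
  col <- rep(NA_real_, length(av))
  col[ok] <- rank_percentiles(av[ok], ids = properties$protein_id[ok])
  out$net_charge_abs <- col
  out
}
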