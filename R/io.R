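#' Read a protein FASTA file into a catalogue
#'
#' Sequences are upper-cased on read. Identifiers are the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description. Residues outside the 20 standard amino acids plus the
#' ambiguity code `X` are rejected.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id`, `sequence`, `description`,
#'   in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a porin", "MKRPLAK"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    abort("FASTA record with empty identifier")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", dup[[1]]))
  }
  seqs <- toupper(as.character(raw))
  names(seqs) <- NULL
  for (i in seq_along(seqs)) {
    check_sequence(seqs[[i]], ids[[i]])
  }
  tibble(protein_id = ids, sequence = seqs, description = descriptions)
}

check_sequence <- function(sequence, protein_id) {
  if (nchar(sequence) < 1) {
    abort(paste0("empty sequence for ", protein_id))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET_X)
  if (length(bad) > 0) {
    abort(sprintf("illegal residue '%s' at position %d in %s",
                  chars[bad[[1]]], bad[[1]], protein_id))
  }
  invisible(TRUE)
}

#' Write a protein catalogue to FASTA
#'
#' Lines are wrapped at 60 columns so that `write_fasta(read_fasta(f))`
#' round-trips sequences and identifiers.
#'
#' @param catalogue Tibble with `protein_id`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalogue, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(catalogue)))
  x <- Biostrings::AAStringSet(catalogue$sequence)
  desc <- catalogue$description %||% rep("", nrow(catalogue))
  if (is.null(catalogue[["description"]])) desc <- rep("", nrow(catalogue))
  names(x) <- ifelse(desc == "", catalogue$protein_id,
                     paste(catalogue$protein_id, desc))
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

quant_col_types <- function() {
  readr::cols(
    protein_id = readr::col_character(),
    approach = readr::col_character(),
    replicate = readr::col_integer(),
    intensity = readr::col_double(),
    approach_group_id = readr::col_character()
  )
}

#' Read a per-approach protein quantification table
#'
#' Tab-separated with columns `protein_id`, `approach`, `replicate`,
#' `intensity`, `approach_group_id`. Approaches must be one of `whole`,
#' `shaved`, `supernatant`; intensities must be non-negative and each
#' (protein, approach, replicate) may occur only once.
#'
#' @param path Path to the quantification TSV.
#' @return A tibble of quantification rows.
#' @export
read_quant <- function(path) {
  q <- readr::read_tsv(path, col_types = quant_col_types(),
                       progress = FALSE)
  validate_quant(q)
}

validate_quant <- function(q) {
  required <- c("protein_id", "approach", "replicate", "intensity",
                "approach_group_id")
  missing_cols <- setdiff(required, names(q))
  if (length(missing_cols) > 0) {
    abort(paste0("quant table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_appr <- setdiff(unique(q$approach), APPROACHES)
  if (length(bad_appr) > 0) {
    abort(paste0("unknown approach: ", paste(bad_appr, collapse = ", ")))
  }
  if (any(!is.finite(q$intensity)) || any(q$intensity < 0)) {
    abort("intensity must be a non-negative finite number")
  }
  if (any(q$replicate < 1)) {
    abort("replicate must be a positive integer")
  }
  key <- paste(q$protein_id, q$approach, q$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate quant row for (protein, approach, replicate): ",
                 key[duplicated(key)][[1]]))
  }
  as_tibble(q)
}

#' Read an annotation table
#'
#' Tab-separated with columns `protein_id`, `signal_peptide` (true/false),
#' `tm_count`, `psortb_location`, `deeplocpro_location`, `phylum`, `class`,
#' `genus`, `cog`. Location strings are normalized to the Gram-negative
#' vocabulary via the shipped mapping file (see [normalize_location()]);
#' unmatched labels become `unknown` with a warning.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path) {
  a <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    signal_peptide = readr::col_logical(),
    tm_count = readr::col_integer(),
    psortb_location = readr::col_character(),
    deeplocpro_location = readr::col_character(),
    phylum = readr::col_character(),
    class = readr::col_character(),
    genus = readr::col_character(),
    cog = readr::col_character()
  ), progress = FALSE, na = character())
  validate_annotations(a)
}

validate_annotations <- function(a) {
  if (anyDuplicated(a$protein_id)) {
    abort(paste0("duplicate annotation row for ",
                 a$protein_id[duplicated(a$protein_id)][[1]]))
  }
  if (any(is.na(a$signal_peptide))) {
    abort("signal_peptide must be true/false")
  }
  if (any(is.na(a$tm_count)) || any(a$tm_count < 0)) {
    abort("tm_count must be a non-negative integer")
  }
  a$psortb_location <- normalize_location(a$psortb_location)
  a$deeplocpro_location <- normalize_location(a$deeplocpro_location)
  a$cog <- toupper(ifelse(is.na(a$cog), "", a$cog))
  bad_cog <- grepl("[^A-Z]", a$cog) |
    vapply(strsplit(a$cog, ""), anyDuplicated, 0L) > 0
  if (any(bad_cog)) {
    abort(paste0("malformed cog string for ", a$protein_id[bad_cog][[1]]))
  }
  for (col in c("phylum", "class", "genus")) {
    a[[col]] <- ifelse(is.na(a[[col]]) | a[[col]] == "",
                       "unclassified", a[[col]])
  }
  as_tibble(a)
}

location_map <- function() {
  path <- system.file("extdata", "location_map.tsv", package = "secretome")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Normalize predictor location labels
#'
#' Maps the heterogeneous vocabularies of subcellular-location predictors
#' onto the 6-label Gram-negative set (`cytoplasmic`, `cytoplasmic_membrane`,
#' `periplasmic`, `cell_wall`, `outer_membrane`, `extracellular`) plus
#' `unknown`. Matching is case-insensitive and ignores spaces, hyphens and
#' underscores; anything unmatched becomes `unknown` with a warning.
#'
#' @param x Character vector of raw predictor labels.
#' @return Character vector of canonical labels.
#' @export
normalize_location <- function(x) {
  canon <- function(s) gsub("[ _-]", "", tolower(s))
  map <- location_map()
  lookup <- setNames(map$canonical, canon(map$label))
  key <- canon(ifelse(is.na(x), "unknown", x))
  out <- unname(lookup[key])
  unmatched <- is.na(out)
  if (any(unmatched)) {
    warn(paste0("unrecognized location label(s) mapped to unknown: ",
                paste(unique(x[unmatched]), collapse = ", ")))
    out[unmatched] <- "unknown"
  }
  out
}

#' Read a per-residue structure table
#'
#' Tab-separated with columns `protein_id`, `position` (1-based), `ss_class`
#' (H/E/C), `rsa` and `disorder` (both in \[0,1\]).
#'
#' @param path Path to the structure TSV.
#' @return A tibble of per-residue rows.
#' @export
read_structure <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    ss_class = readr::col_character(),
    rsa = readr::col_double(),
    disorder = readr::col_double()
  ), progress = FALSE)
  validate_structure(s)
}

validate_structure <- function(s) {
  if (any(!s$ss_class %in% c("H", "E", "C"))) {
    abort("ss_class must be one of H, E, C")
  }
  if (any(s$rsa < 0 | s$rsa > 1) || any(s$disorder < 0 | s$disorder > 1)) {
    abort("rsa and disorder must lie in [0, 1]")
  }
  s <- arrange(s, .data$protein_id, .data$position)
  bad <- s %>%
    group_by(.data$protein_id) %>%
    summarise(contiguous = all(.data$position == seq_len(n())),
              .groups = "drop") %>%
    filter(!.data$contiguous)
  if (nrow(bad) > 0) {
    abort(paste0("structure positions not contiguous from 1 for ",
                 bad$protein_id[[1]]))
  }
  as_tibble(s)
}

#' Read and cross-validate a full dataset
#'
#' Reads the FASTA catalogue, quantification, annotation and structure
#' tables, checks referential integrity, and fills default annotations
#' (no signal peptide, no transmembrane domain, unknown locations, empty
#' taxonomy and COG) for catalogue proteins lacking an annotation row.
#'
#' @param fasta,quant,annot,struct Paths to the four input files.
#' @return A list of class `secretome_dataset` with elements `catalogue`,
#'   `quant`, `annotations`, `structure` and `validation` (a tibble listing
#'   defaulted/flagged protein ids). Row order of the tabular inputs does
#'   not affect the result.
#' @export
read_dataset <- function(fasta, quant, annot, struct) {
  catalogue <- read_fasta(fasta)
  q <- read_quant(quant)
  a <- read_annotations(annot)
  s <- read_structure(struct)
  build_dataset(catalogue, q, a, s)
}

#' Assemble and validate a dataset from in-memory tables
#'
#' @param catalogue,quant,annotations,structure Tibbles in the schemas of
#'   [read_fasta()], [read_quant()], [read_annotations()] and
#'   [read_structure()].
#' @return See [read_dataset()].
#' @export
build_dataset <- function(catalogue, quant, annotations, structure) {
  quant <- validate_quant(quant)
  annotations <- validate_annotations(annotations)
  structure <- validate_structure(structure)
  ids <- catalogue$protein_id

  unknown_q <- setdiff(unique(quant$protein_id), ids)
  if (length(unknown_q) > 0) {
    abort(paste0("quant references unknown protein_id: ", unknown_q[[1]]))
  }
  unknown_a <- setdiff(unique(annotations$protein_id), ids)
  if (length(unknown_a) > 0) {
    abort(paste0("annotations reference unknown protein_id: ",
                 unknown_a[[1]]))
  }
  unknown_s <- setdiff(unique(structure$protein_id), ids)
  if (length(unknown_s) > 0) {
    abort(paste0("structure references unknown protein_id: ",
                 unknown_s[[1]]))
  }

  len <- setNames(nchar(catalogue$sequence), ids)
  slen <- structure %>% count(.data$protein_id, name = "rows")
  mism <- slen$rows != len[slen$protein_id]
  if (any(mism)) {
    p <- slen$protein_id[mism][[1]]
    abort(sprintf("length mismatch %s: %d vs %d", p,
                  slen$rows[mism][[1]], len[[p]]))
  }

  defaulted <- setdiff(ids, annotations$protein_id)
  if (length(defaulted) > 0) {
    annotations <- bind_rows(annotations, tibble(
      protein_id = defaulted,
      signal_peptide = FALSE,
      tm_count = 0L,
      psortb_location = "unknown",
      deeplocpro_location = "unknown",
      phylum = "unclassified",
      class = "unclassified",
      genus = "unclassified",
      cog = ""
    ))
  }
  no_quant <- setdiff(ids, unique(quant$protein_id))
  no_struct <- setdiff(ids, unique(structure$protein_id))

  validation <- bind_rows(
    tibble(protein_id = defaulted, issue = "annotation_defaulted"),
    tibble(protein_id = no_quant, issue = "not_quantified"),
    tibble(protein_id = no_struct, issue = "no_structure")
  ) %>% arrange(.data$issue, .data$protein_id)

  out <- list(
    catalogue = catalogue,
    quant = arrange(quant, .data$protein_id, .data$approach,
                    .data$replicate),
    annotations = arrange(annotations, .data$protein_id),
    structure = arrange(structure, .data$protein_id, .data$position),
    validation = validation
  )
  class(out) <- "secretome_dataset"
  out
}

#' @export
print.secretome_dataset <- function(x, ...) {
  cat("<secretome_dataset>\n")
  cat("  proteins:   ", nrow(x$catalogue), "\n")
  cat("  quant rows: ", nrow(x$quant), " (",
      paste(sort(unique(x$quant$approach)), collapse = ", "), ")\n",
      sep = "")
  cat("  structure:  ", length(unique(x$structure$protein_id)),
      "proteins\n")
  cat("  validation: ", nrow(x$validation), "flagged ids\n")
  invisible(x)
}
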