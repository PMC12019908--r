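# small in-memory dataset used by io / localization / rollup tests

tiny_catalogue <- function() {
  tibble::tibble(
    protein_id = c("pA", "pB", "pC", "pD"),
    sequence = c("MKRPLAKAAWCF", "AAKAARPK", "CCWWYYKK", "MKAAAAAAKLLLLLLLR"),
    description = c("porin-like", "background", "cys-rich", "long helix")
  )
}

tiny_annotations <- function() {
  tibble::tibble(
    protein_id = c("pA", "pB", "pC", "pD"),
    signal_peptide = c(TRUE, FALSE, FALSE, FALSE),
    tm_count = c(0L, 2L, 0L, 0L),
    psortb_location = c("outer_membrane", "cytoplasmic",
                        "extracellular", "cytoplasmic"),
    deeplocpro_location = c("outer_membrane", "cytoplasmic",
                            "extracellular", "unknown"),
    phylum = c("Pseudomonadota", "Pseudomonadota", "Bacteroidota",
               "Pseudomonadota"),
    class = c("Betaproteobacteria", "Betaproteobacteria", "Flavobacteriia",
              "Gammaproteobacteria"),
    genus = c("Ca_Accumulibacter", "Dechloromonas", "Flavobacterium",
              "Competibacter"),
    cog = c("M", "", "NU", "C")
  )
}

tiny_structure <- function() {
  cat_ <- tiny_catalogue()
  dplyr::bind_rows(lapply(seq_len(nrow(cat_)), function(i) {
    L <- nchar(cat_$sequence[[i]])
    tibble::tibble(
      protein_id = cat_$protein_id[[i]],
      position = seq_len(L),
      ss_class = rep(c("E", "H", "C"), length.out = L),
      rsa = round(seq(0.1, 0.9, length.out = L), 4),
      disorder = rep(0.25, L)
    )
  }))
}

tiny_quant <- function() {
  grid <- expand.grid(protein_id = c("pA", "pB", "pC", "pD"),
                      approach = c("whole", "shaved", "supernatant"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  base <- c(pA = 600, pB = 50, pC = 200, pD = 400)
  grid$intensity <- base[grid$protein_id] *
    ifelse(grid$approach == "supernatant" &
             grid$protein_id %in% c("pA", "pC"), 4, 1)
  grid$replicate <- as.integer(grid$replicate)
  grid$approach_group_id <- paste0(substr(grid$approach, 1, 2), "_",
                                   grid$protein_id)
  tibble::as_tibble(grid)
}

tiny_dataset <- function() {
  build_dataset(tiny_catalogue(), tiny_quant(), tiny_annotations(),
                tiny_structure())
}
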