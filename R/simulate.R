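#' Default simulation configuration
#'
#' Describes a synthetic granular-enrichment metaproteome: a metagenome-like
#' protein catalogue with log-normal lengths, log-normal abundances with
#' approach-specific enrichment of secreted proteins (whole-granule vs
#' shaved vs supernatant), predictor-style annotations consistent with the
#' true locations, per-residue structure tables, and a planted subset of
#' proteins with extreme aggregate-forming properties plus matched decoys.
#' All randomness flows from `seed` through named substreams so stages can
#' be regenerated independently.
#'
#' @param n_proteins Catalogue size (default 500).
#' @param seed Integer seed controlling every draw (default 42).
#' @param n_planted_true Planted true candidates: extreme property,
#'   secreted, abundant (default 25).
#' @param n_planted_decoy Planted decoys: extreme property but either
#'   intracellular or low-abundance (default 25, split between the two
#'   decoy roles).
#' @param ... Overrides for any other config entry.
#' @return A nested list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500, seed = 42,
                       n_planted_true = 25, n_planted_decoy = 25, ...) {
  cfg <- list(
    n_proteins = n_proteins,
    seed = seed,
    n_planted_true = n_planted_true,
    n_planted_decoy = n_planted_decoy,
    length_meanlog = log(300),
    length_sdlog = 0.5,
    min_length = 30,
    location_priors = c(cytoplasmic = 0.6, periplasmic = 0.1,
                        outer_membrane = 0.1, extracellular = 0.1,
                        cytoplasmic_membrane = 0.1),
    # log10 abundance base: N(0, 1.5)
    abundance_mu = 0,
    abundance_sigma = 1.5,
    replicate_sigma = 0.1,
    replicates = c(whole = 2L, shaved = 3L, supernatant = 3L),
    enrichment = rbind(
      cytoplasmic          = c(whole = 1, shaved = 0.1, supernatant = 0.1),
      cytoplasmic_membrane = c(whole = 1, shaved = 1.0, supernatant = 0.5),
      periplasmic          = c(whole = 1, shaved = 3.0, supernatant = 2.0),
      cell_wall            = c(whole = 1, shaved = 3.0, supernatant = 2.0),
      outer_membrane       = c(whole = 1, shaved = 3.0, supernatant = 4.0),
      extracellular        = c(whole = 1, shaved = 5.0, supernatant = 8.0)
    ),
    detection = rbind(
      cytoplasmic          = c(whole = 0.95, shaved = 0.35, supernatant = 0.45),
      cytoplasmic_membrane = c(whole = 0.95, shaved = 0.50, supernatant = 0.40),
      periplasmic          = c(whole = 0.95, shaved = 0.70, supernatant = 0.60),
      cell_wall            = c(whole = 0.95, shaved = 0.60, supernatant = 0.60),
      outer_membrane       = c(whole = 0.95, shaved = 0.80, supernatant = 0.80),
      extracellular        = c(whole = 0.95, shaved = 0.90, supernatant = 0.95)
    ),
    sp_prob = c(cytoplasmic = 0.02, cytoplasmic_membrane = 0.3,
                periplasmic = 0.7, cell_wall = 0.6,
                outer_membrane = 0.6, extracellular = 0.9),
    tm_lambda = c(cytoplasmic = 0.05, cytoplasmic_membrane = 3,
                  periplasmic = 0.1, cell_wall = 0.1,
                  outer_membrane = 0.8, extracellular = 0.1),
    predictor_accuracy = 0.8,
    structure_missing_rate = 0.02,
    genus_shares = c(Ca_Accumulibacter = 0.60, Dechloromonas = 0.07,
                     Thauera = 0.05, Hydrogenophaga = 0.08,
                     Competibacter = 0.05, Flavobacterium = 0.05,
                     unclassified = 0.10),
    cog_pool = c("C", "E", "G", "M", "N", "NU", "P", "T", "S", "",
                 "MG", "O", "J", "U"),
    cog_weights = c(8, 5, 5, 10, 3, 3, 5, 6, 10, 15, 2, 4, 6, 3),
    group_pair_rate = 0.04,
    group_merge_rate = 0.02,
    group_conflict_rate = 0.01
  )
  override <- list(...)
  cfg[names(override)] <- override
  if (abs(sum(cfg$location_priors) - 1) > 1e-9) {
    abort("location priors must sum to 1")
  }
  if (cfg$n_planted_true + cfg$n_planted_decoy > cfg$n_proteins) {
    abort("planted proteins exceed n_proteins")
  }
  class(cfg) <- "sim_config"
  cfg
}

# background amino-acid frequencies (roughly bacterial proteome-wide)
background_aa_profile <- function() {
  p <- c(A = 8.8, R = 5.0, N = 3.9, D = 5.4, C = 1.2, Q = 3.9, E = 6.7,
         G = 7.4, H = 2.2, I = 5.7, L = 10.2, K = 5.8, M = 2.4, F = 4.0,
         P = 4.7, S = 6.4, T = 5.4, V = 7.0, W = 1.1, X = 0.4, Y = 3.0)
  p / sum(p)
}

# composition profiles for the planted extreme types; structural extremes
# reuse the background composition and act through the structure tables
extreme_profiles <- function() {
  bg <- background_aa_profile()
  tweak <- function(boost) {
    p <- bg
    p[names(boost)] <- boost
    p / sum(p)
  }
  list(
    hydrophobic = tweak(c(I = 15, L = 18, V = 14, A = 12, F = 8) / 100),
    aromatic = tweak(c(F = 14, W = 8, Y = 10) / 100),
    cysteine = tweak(c(C = 15) / 100),
    # keep K/R at digestible levels so tryptic iBAQ stays defined
    charge_positive = tweak(c(K = 18, R = 14, D = 1, E = 1) / 100),
    charge_negative = tweak(c(D = 16, E = 16, K = 4, R = 4) / 100),
    length = bg,
    beta_sheet = bg,
    low_rsa = bg,
    low_disorder = bg
  )
}

EXTREME_TYPES <- c("hydrophobic", "beta_sheet", "cysteine", "aromatic",
                   "length", "charge_positive", "charge_negative",
                   "low_rsa", "low_disorder")

sub_seed <- function(seed, stream) {
  offsets <- c(roles = 11L, sequences = 23L, abundance = 37L,
               annotations = 53L, structure = 71L, grouping = 89L)
  (seed %% 100000L) * 1000L + offsets[[stream]]
}

#' Generate a synthetic metaproteome dataset with planted ground truth
#'
#' Emulates the statistical structure the analysis pipeline assumes: a
#' protein catalogue with composition-driven sequences, three quantification
#' approaches whose abundances favour secreted proteins to different
#' degrees, predictor-style annotations, per-residue structure tables, and
#' planted proteins with extreme aggregate-forming properties. Planted
#' `true_candidate` proteins are secreted-or-extracellular with top-half
#' abundance by construction; `decoy_intracellular` proteins are extreme
#' but cytoplasmic, `decoy_low_abundance` proteins extreme and secreted but
#' vanishingly scarce.
#'
#' @param config A [sim_config()].
#' @return A list of class `secretome_simulation`: `dataset` (a validated
#'   `secretome_dataset`), `truth` (tibble with `protein_id`,
#'   `true_location`, `planted_role`, `extreme_property`, per-approach
#'   enrichment factors), and `config`.
#' @export
simulate_metaproteome <- function(config = sim_config()) {
  n <- config$n_proteins
  ids <- sprintf("prot_%04d", seq_len(n))

  ## roles, locations, extreme types -----------------------------------
  set.seed(sub_seed(config$seed, "roles"))
  n_true <- config$n_planted_true
  n_decoy <- config$n_planted_decoy
  n_dec_intra <- ceiling(n_decoy / 2)
  n_dec_low <- n_decoy - n_dec_intra
  planted_idx <- sample.int(n, n_true + n_decoy)
  role <- rep("none", n)
  role[planted_idx[seq_len(n_true)]] <- "true_candidate"
  role[planted_idx[n_true + seq_len(n_dec_intra)]] <- "decoy_intracellular"
  if (n_dec_low > 0) {
    role[planted_idx[n_true + n_dec_intra + seq_len(n_dec_low)]] <-
      "decoy_low_abundance"
  }
  extreme <- rep("none", n)
  extreme[planted_idx] <- rep_len(EXTREME_TYPES, n_true + n_decoy)

  location <- sample(names(config$location_priors), n, replace = TRUE,
                     prob = config$location_priors)
  location[role %in% c("true_candidate", "decoy_low_abundance")] <-
    "extracellular"
  location[role == "decoy_intracellular"] <- "cytoplasmic"

  ## sequences -----------------------------------------------------------
  set.seed(sub_seed(config$seed, "sequences"))
  lens <- pmax(config$min_length,
               round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  long_planted <- extreme == "length"
  lens[long_planted] <- round(rlnorm(sum(long_planted), log(3000), 0.2))
  profiles <- extreme_profiles()
  bg <- background_aa_profile()
  sequences <- vapply(seq_len(n), function(i) {
    p <- if (extreme[[i]] == "none") bg else profiles[[extreme[[i]]]]
    paste0(sample(names(p), lens[[i]], replace = TRUE, prob = p),
           collapse = "")
  }, "")

  catalogue <- tibble(protein_id = ids, sequence = sequences,
                      description = paste0("synthetic ", role))

  ## abundances ----------------------------------------------------------
  set.seed(sub_seed(config$seed, "abundance"))
  log_base <- rnorm(n, config$abundance_mu, config$abundance_sigma)
  log_base[role == "true_candidate"] <- rnorm(sum(role == "true_candidate"),
                                              3, 0.3)
  log_base[role == "decoy_low_abundance"] <-
    rnorm(sum(role == "decoy_low_abundance"), -5, 0.3)
  base <- 10^log_base

  detected <- matrix(FALSE, n, length(APPROACHES),
                     dimnames = list(ids, APPROACHES))
  for (a in APPROACHES) {
    p_det <- config$detection[location, a]
    detected[, a] <- runif(n) < p_det
  }
  detected[role != "none", ] <- TRUE  # planted proteins always observed

  quant_rows <- list()
  for (a in APPROACHES) {
    enr <- config$enrichment[location, a]
    for (r in seq_len(config$replicates[[a]])) {
      noise <- 10^rnorm(n, 0, config$replicate_sigma)
      keep <- detected[, a]
      quant_rows[[length(quant_rows) + 1]] <- tibble(
        protein_id = ids[keep],
        approach = a,
        replicate = as.integer(r),
        intensity = (base * enr * noise)[keep]
      )
    }
  }
  quant <- bind_rows(quant_rows)

  ## annotations ---------------------------------------------------------
  set.seed(sub_seed(config$seed, "annotations"))
  sp <- runif(n) < config$sp_prob[location]
  sp[role %in% c("true_candidate", "decoy_low_abundance")] <- TRUE
  sp[role == "decoy_intracellular"] <- FALSE
  tm <- rpois(n, config$tm_lambda[location])

  predict_location <- function() {
    correct <- runif(n) < config$predictor_accuracy
    out <- location
    wrong <- which(!correct)
    alt <- vapply(wrong, function(i) {
      sample(setdiff(LOCATION_LEVELS, location[[i]]), 1)
    }, "")
    out[wrong] <- alt
    out
  }
  loc_a <- predict_location()
  loc_b <- predict_location()
  # decoy predictors must not claim extracellular: clause (iii) is part of
  # the planted ground truth, not a roll of the predictor dice
  intra <- role == "decoy_intracellular"
  loc_a[intra & loc_a == "extracellular"] <- "cytoplasmic"
  loc_b[intra & loc_b == "extracellular"] <- "cytoplasmic"

  lineage <- tibble::tribble(
    ~genus, ~class, ~phylum,
    "Ca_Accumulibacter", "Betaproteobacteria", "Pseudomonadota",
    "Dechloromonas", "Betaproteobacteria", "Pseudomonadota",
    "Thauera", "Betaproteobacteria", "Pseudomonadota",
    "Hydrogenophaga", "Betaproteobacteria", "Pseudomonadota",
    "Competibacter", "Gammaproteobacteria", "Pseudomonadota",
    "Flavobacterium", "Flavobacteriia", "Bacteroidota",
    "unclassified", "unclassified", "unclassified"
  )
  genus <- sample(names(config$genus_shares), n, replace = TRUE,
                  prob = config$genus_shares)
  tax <- tibble(genus = genus) %>% left_join(lineage, by = "genus")
  cog <- sample(config$cog_pool, n, replace = TRUE,
                prob = config$cog_weights)

  annotations <- tibble(
    protein_id = ids,
    signal_peptide = sp,
    tm_count = as.integer(tm),
    psortb_location = loc_a,
    deeplocpro_location = loc_b,
    phylum = tax$phylum,
    class = tax$class,
    genus = tax$genus,
    cog = cog
  )

  ## structure -----------------------------------------------------------
  set.seed(sub_seed(config$seed, "structure"))
  beta_t <- rbeta(n, 2, 8)
  beta_t[extreme == "beta_sheet"] <- rbeta(sum(extreme == "beta_sheet"),
                                           8, 2)
  rsa_t <- rbeta(n, 5, 5)
  rsa_t[extreme == "low_rsa"] <- rbeta(sum(extreme == "low_rsa"), 1.5, 20)
  dis_t <- rbeta(n, 4, 8)
  dis_t[extreme == "low_disorder"] <- rbeta(sum(extreme == "low_disorder"),
                                            1.5, 25)
  has_struct <- runif(n) >= config$structure_missing_rate
  has_struct[role != "none"] <- TRUE  # planted proteins need full vectors

  conc <- 10  # per-residue beta concentration around the protein target
  struct_list <- lapply(which(has_struct), function(i) {
    L <- lens[[i]]
    ss <- sample(c("E", "H", "C"), L, replace = TRUE,
                 prob = c(beta_t[[i]], 0.4 * (1 - beta_t[[i]]),
                          0.6 * (1 - beta_t[[i]])))
    tibble(
      protein_id = ids[[i]],
      position = seq_len(L),
      ss_class = ss,
      rsa = round(rbeta(L, conc * rsa_t[[i]],
                        conc * (1 - rsa_t[[i]])), 4),
      disorder = round(rbeta(L, conc * dis_t[[i]],
                             conc * (1 - dis_t[[i]])), 4)
    )
  })
  structure <- bind_rows(struct_list)

  ## approach-specific protein groups ------------------------------------
  set.seed(sub_seed(config$seed, "grouping"))
  true_group <- seq_len(n)
  pairable <- which(runif(n) < config$group_pair_rate)
  for (i in pairable) {
    j <- if (i < n) i + 1L else i - 1L
    true_group[[j]] <- true_group[[i]]
  }
  gid_of <- function(a) sprintf("%s_g%04d", substr(a, 1, 2), true_group)
  gids <- sapply(APPROACHES, gid_of)
  colnames(gids) <- APPROACHES

  both <- which(detected[, "whole"] & detected[, "shaved"] &
                  role == "none")
  n_merge <- round(config$group_merge_rate * n)
  n_conflict <- round(config$group_conflict_rate * n)
  pick <- if (length(both) >= 2 * (n_merge + n_conflict)) {
    sample(both, 2 * (n_merge + n_conflict))
  } else integer()
  merge_pairs <- conflict_pairs <- list()
  if (length(pick) > 0) {
    for (m in seq_len(n_merge)) {
      i <- pick[[2 * m - 1]]; j <- pick[[2 * m]]
      gids[j, "shaved"] <- gids[i, "shaved"]  # extra cross-link evidence
      merge_pairs[[m]] <- c(ids[[i]], ids[[j]])
    }
    for (m in seq_len(n_conflict)) {
      i <- pick[[2 * n_merge + 2 * m - 1]]; j <- pick[[2 * n_merge + 2 * m]]
      gids[j, "shaved"] <- gids[i, "shaved"]  # linked in shaved ...
      # ... but they keep distinct whole-granule groups: a conflict the
      # canonical-order merge must skip
      conflict_pairs[[m]] <- c(ids[[i]], ids[[j]])
    }
  }
  quant$approach_group_id <- gids[cbind(match(quant$protein_id, ids),
                                        match(quant$approach, APPROACHES))]

  dataset <- build_dataset(catalogue, quant, annotations, structure)

  truth <- tibble(
    protein_id = ids,
    true_location = location,
    planted_role = role,
    extreme_property = extreme,
    enrich_whole = config$enrichment[location, "whole"],
    enrich_shaved = config$enrichment[location, "shaved"],
    enrich_supernatant = config$enrichment[location, "supernatant"]
  )

  out <- list(dataset = dataset, truth = truth, config = config)
  class(out) <- "secretome_simulation"
  out
}

#' Write a simulated dataset to disk
#'
#' Emits `proteins.fasta`, `quant.tsv`, `annotations.tsv`, `structure.tsv`
#' and `truth.tsv` in the schemas consumed by [read_dataset()].
#'
#' @param sim Output of [simulate_metaproteome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  write_fasta(ds$catalogue, file.path(dir, "proteins.fasta"))
  readr::write_tsv(ds$quant, file.path(dir, "quant.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$annotations, file.path(dir, "annotations.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$structure, file.path(dir, "structure.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Simulate limited proteolysis ("shaving") of a catalogue
#'
#' Surface-exposed proteins release semi-specific peptides when intact
#' granules are incubated with a protease. Each peptide of the
#' semi-specific digest (4 missed cleavages by default) is retained with
#' probability `digestibility(location) * subsample_fraction`, so the
#' expected peptide yield scales linearly with the location's exposure.
#'
#' @param catalogue Tibble with `protein_id`, `sequence`.
#' @param truth Tibble with `protein_id`, `true_location` (as produced by
#'   [simulate_metaproteome()]).
#' @param protease Protease regime (default `"trypsin"`).
#' @param exposure_model Named vector mapping location to digestibility
#'   probability.
#' @param subsample_fraction Fraction of the accessible digest sampled
#'   (default 1).
#' @param max_missed,length_range Passed to [digest()].
#' @param seed Seed for the peptide subsampling.
#' @return Peptide tibble (`protein_id`, `start`, `end`, `sequence`,
#'   `n_missed`, `specificity`).
#' @export
simulate_shaving <- function(catalogue, truth, protease = "trypsin",
                             exposure_model = c(
                               extracellular = 0.9, outer_membrane = 0.6,
                               cell_wall = 0.5, periplasmic = 0.4,
                               cytoplasmic_membrane = 0.2,
                               cytoplasmic = 0.02),
                             subsample_fraction = 1,
                             max_missed = 4, length_range = c(7, 30),
                             seed = 1L) {
  set.seed(seed)
  loc <- setNames(truth$true_location, truth$protein_id)
  out <- lapply(seq_len(nrow(catalogue)), function(i) {
    id <- catalogue$protein_id[[i]]
    dig <- unname(exposure_model[loc[[id]]])
    if (is.na(dig)) dig <- 0
    p_keep <- dig * subsample_fraction
    if (p_keep <= 0) return(NULL)
    peps <- digest(catalogue$sequence[[i]], protease,
                   max_missed = max_missed, mode = "semispecific",
                   length_range = length_range)
    if (nrow(peps) == 0) return(NULL)
    keep <- runif(nrow(peps)) < p_keep
    if (!any(keep)) return(NULL)
    mutate(peps[keep, ], protein_id = id, .before = 1)
  })
  bind_rows(out)
}
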