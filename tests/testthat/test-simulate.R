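test_that("simulation is fully determined by its seed", {
  cfg <- sim_config(n_proteins = 120, seed = 7, n_planted_true = 6,
                    n_planted_decoy = 6)
  s1 <- simulate_metaproteome(cfg)
  s2 <- simulate_metaproteome(cfg)
  expect_equal(s1$dataset$catalogue, s2$dataset$catalogue)
  expect_equal(s1$dataset$quant, s2$dataset$quant)
  expect_equal(s1$dataset$structure, s2$dataset$structure)
  expect_equal(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  s3 <- simulate_metaproteome(sim_config(n_proteins = 120, seed = 8,
                                         n_planted_true = 6,
                                         n_planted_decoy = 6))
  expect_false(identical(s1$dataset$quant$intensity,
                         s3$dataset$quant$intensity))
})

test_that("planted roles honour their construction invariants", {
  sim <- simulate_metaproteome(sim_config(n_proteins = 200, seed = 3,
                                          n_planted_true = 10,
                                          n_planted_decoy = 10))
  truth <- sim$truth
  expect_equal(sum(truth$planted_role == "true_candidate"), 10)
  expect_equal(sum(grepl("^decoy", truth$planted_role)), 10)

  annot <- sim$dataset$annotations
  sec <- classify_secretion(annot)
  tp <- truth$protein_id[truth$planted_role == "true_candidate"]
  expect_true(all(sec$secreted_or_extracellular[sec$protein_id %in% tp]))
  di <- truth$protein_id[truth$planted_role == "decoy_intracellular"]
  expect_false(any(sec$secreted_or_extracellular[sec$protein_id %in% di]))

  # planted true candidates sit in the top abundance half of an approach
  conv <- ibaq_convert(sim$dataset$quant, sim$dataset$catalogue,
                       c(whole = "trypsin", shaved = "trypsin",
                         supernatant = "trypsin"))
  pct <- approach_mean_ibaq(conv$abundance) %>%
    dplyr::group_by(approach) %>%
    dplyr::mutate(pct = rank(ibaq) / dplyr::n()) %>%
    dplyr::ungroup()
  top_half <- pct %>%
    dplyr::filter(pct > 0.5) %>%
    dplyr::pull(protein_id)
  expect_true(all(tp %in% top_half))
  dl <- truth$protein_id[truth$planted_role == "decoy_low_abundance"]
  expect_false(any(dl %in% top_half))
})

test_that("rejecting over-planted configurations", {
  expect_error(sim_config(n_proteins = 10, n_planted_true = 8,
                          n_planted_decoy = 8), "exceed")
  expect_error(sim_config(location_priors = c(cytoplasmic = 0.5)),
               "sum to 1")
})

test_that("approach enrichment shows up in the secreted biomass shares", {
  # supernatant enriches extracellular proteins over whole granules in
  # most seeds (sign test over several replicated worlds)
  wins <- 0
  for (seed in 1:8) {
    sim <- simulate_metaproteome(sim_config(n_proteins = 150, seed = seed,
                                            n_planted_true = 5,
                                            n_planted_decoy = 5))
    conv <- ibaq_convert(sim$dataset$quant, sim$dataset$catalogue,
                         c(whole = "trypsin", shaved = "trypsin",
                           supernatant = "trypsin"))
    sec <- classify_secretion(sim$dataset$annotations)
    sh <- biomass_fractions(
      conv$abundance,
      tibble::tibble(protein_id = sec$protein_id,
                     key = ifelse(sec$secreted_or_extracellular,
                                  "sec", "other")))
    s_sup <- sh$share[sh$approach == "supernatant" & sh$key == "sec"]
    s_whole <- sh$share[sh$approach == "whole" & sh$key == "sec"]
    wins <- wins + (s_sup > s_whole)
  }
  expect_gte(wins, 7)
})

test_that("shaving peptide yield follows the exposure model", {
  cat_ <- tibble::tibble(
    protein_id = c("cyt1", "ext1"),
    sequence = c(strrep("AKAAAAAAAA", 6), strrep("AAAARAAAAA", 6)))
  truth <- tibble::tibble(protein_id = c("cyt1", "ext1"),
                          true_location = c("cytoplasmic", "extracellular"))
  # digestibility zero: nothing shaves off
  none <- simulate_shaving(cat_, truth,
                           exposure_model = c(cytoplasmic = 0,
                                              extracellular = 0))
  expect_equal(nrow(none), 0)
  # digestibility one, full subsample: the entire semispecific digest
  full <- simulate_shaving(cat_[2, ], truth,
                           exposure_model = c(extracellular = 1),
                           subsample_fraction = 1)
  want <- digest(cat_$sequence[[2]], "trypsin", 4, "semispecific")
  expect_equal(nrow(full), nrow(want))
  # expected yield scales about linearly with digestibility
  yields <- vapply(c(0.25, 0.5, 1), function(d) {
    mean(vapply(1:20, function(s) {
      nrow(simulate_shaving(cat_[2, ], truth,
                            exposure_model = c(extracellular = d),
                            subsample_fraction = 0.5, seed = s))
    }, 0))
  }, 0)
  expect_equal(yields[[2]] / yields[[3]], 0.5, tolerance = 0.15)
  expect_equal(yields[[1]] / yields[[3]], 0.25, tolerance = 0.2)
})
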