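test_that("iBAQ conversion divides by the theoretical peptide count", {
  cat_ <- tibble::tibble(
    protein_id = "p1",
    # trypsin: five segments of length 8,8,8,8,7, all inside the window
    sequence = paste0(strrep("AAAAAAAK", 4), "AAAAAAA"))
  expect_equal(theoretical_peptide_count(cat_$sequence, "trypsin"), 5)
  q <- tibble::tibble(protein_id = "p1", approach = "whole",
                      replicate = 1L, intensity = 1e6,
                      approach_group_id = "g1")
  out <- ibaq_convert(q, cat_, c(whole = "trypsin"))
  expect_equal(out$abundance$ibaq, 1e6 / 5)

  # zero intensity stays zero; scaling is linear
  q$intensity <- 0
  expect_equal(ibaq_convert(q, cat_, c(whole = "trypsin"))$abundance$ibaq,
               0)
})

test_that("iBAQ conversion is linear in intensity", {
  ds <- tiny_dataset()
  pr <- c(whole = "trypsin", shaved = "lysc", supernatant = "trypsin")
  a1 <- ibaq_convert(ds$quant, ds$catalogue, pr)$abundance
  q2 <- dplyr::mutate(ds$quant, intensity = intensity * 3.5)
  a2 <- ibaq_convert(q2, ds$catalogue, pr)$abundance
  expect_equal(a2$ibaq, a1$ibaq * 3.5)
})

test_that("rows without theoretical peptides are dropped and reported", {
  cat_ <- tibble::tibble(protein_id = c("p1", "p2"),
                         sequence = c("AAAAAAAAAA", "AKAKAKAK"))
  q <- tibble::tibble(protein_id = c("p1", "p2"), approach = "whole",
                      replicate = 1L, intensity = c(10, 20),
                      approach_group_id = c("g1", "g2"))
  expect_message(out <- ibaq_convert(q, cat_, c(whole = "trypsin")),
                 "dropped")
  expect_equal(out$abundance$protein_id, "p1")
  expect_equal(out$dropped$protein_id, "p2")
  # unknown catalogue entries are fatal
  q$protein_id[1] <- "pX"
  expect_error(ibaq_convert(q, cat_, c(whole = "trypsin")),
               "absent from catalogue: pX")
})

test_that("per-replicate protease regimes are honoured", {
  cat_ <- tibble::tibble(protein_id = "p1",
                         sequence = "AAAAAAKAAAAAAAAARAAAAAAA")
  # trypsin: segments 7/10/7 -> 3 peptides; lysc: segments 7/17 -> 2
  q <- tibble::tibble(protein_id = "p1", approach = "whole",
                      replicate = c(1L, 2L), intensity = c(30, 30),
                      approach_group_id = "g1")
  meta <- tibble::tibble(approach = "whole", replicate = c(1L, 2L),
                         protease = c("trypsin", "lysc"))
  out <- ibaq_convert(q, cat_, meta)$abundance
  expect_equal(out$ibaq[out$replicate == 1], 10)
  expect_equal(out$ibaq[out$replicate == 2], 15)
})

test_that("taxonomy shares sum to one and refine consistently", {
  ds <- tiny_dataset()
  ab <- ibaq_convert(ds$quant, ds$catalogue,
                     c(whole = "trypsin", shaved = "lysc",
                       supernatant = "trypsin"))$abundance
  for (rank in c("phylum", "class", "genus")) {
    sh <- taxonomy_shares(ab, ds$annotations, rank)
    sums <- tapply(sh$share, sh$approach, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # genus shares aggregate to class shares under a consistent lineage
  g <- taxonomy_shares(ab, ds$annotations, "genus")
  cl <- taxonomy_shares(ab, ds$annotations, "class")
  lineage <- dplyr::distinct(ds$annotations, genus, class)
  agg <- g %>%
    dplyr::left_join(lineage, by = c(key = "genus")) %>%
    dplyr::group_by(approach, class) %>%
    dplyr::summarise(share = sum(share), .groups = "drop")
  merged <- dplyr::inner_join(agg, cl,
                              by = c("approach", class = "key"))
  expect_equal(merged$share.x, merged$share.y, tolerance = 1e-9)
})

test_that("multi-category COG proteins contribute fully to each category", {
  ab <- tibble::tibble(protein_id = c("p1", "p2"), approach = "whole",
                       ibaq = c(6, 4))
  annot <- tibble::tibble(protein_id = c("p1", "p2"),
                          cog = c("M", "NU"))
  out <- cog_shares(ab, annot)
  expect_equal(out$share[out$key == "M"], 0.6)
  expect_equal(out$share[out$key == "N"], 0.4)
  expect_equal(out$share[out$key == "U"], 0.4)
  expect_equal(sum(out$share), 1.4)
})

test_that("no-COG proteins report under NA; single categories sum to one", {
  ab <- tibble::tibble(protein_id = "p1", approach = "shaved", ibaq = 5)
  out <- cog_shares(ab, tibble::tibble(protein_id = "p1", cog = ""))
  expect_equal(out$key, "NA")
  expect_equal(out$share, 1)

  ab2 <- tibble::tibble(protein_id = c("a", "b", "c"), approach = "whole",
                        ibaq = c(1, 2, 3))
  annot2 <- tibble::tibble(protein_id = c("a", "b", "c"),
                           cog = c("C", "M", "S"))
  expect_equal(sum(cog_shares(ab2, annot2)$share), 1)
})

test_that("the secreted COG subset restricts numerator and denominator", {
  ab <- tibble::tibble(protein_id = c("p1", "p2"), approach = "whole",
                       ibaq = c(6, 4))
  annot <- tibble::tibble(protein_id = c("p1", "p2"), cog = c("M", "C"))
  secretion <- tibble::tibble(protein_id = c("p1", "p2"),
                              category = c("SP", "None"),
                              secreted_or_extracellular = c(TRUE, FALSE))
  out <- cog_shares(ab, annot, secretion,
                    subset = "secreted_or_extracellular")
  expect_equal(out$key, "M")
  expect_equal(out$share, 1)
  expect_error(cog_shares(ab, annot, subset = "secreted_or_extracellular"),
               "secretion classes required")
})

test_that("minor categories collapse into Other only in the report layer", {
  sh <- tibble::tibble(approach = "whole", key_type = "cog",
                       key = c("M", "C", "Q"),
                       share = c(0.9, 0.09, 0.01))
  out <- collapse_minor_categories(sh, floor = 0.02)
  expect_setequal(out$key, c("M", "C", "Other"))
  expect_equal(out$share[out$key == "Other"], 0.01)
})
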