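# a rank matrix of n proteins with distinct values; protein "hit" carries
# the maximal gravy percentile
screen_fixture <- function(n = 10) {
  ids <- c(sprintf("bg%02d", seq_len(n - 1)), "hit")
  props <- tibble::tibble(
    protein_id = ids,
    gravy = c(seq(-2, 0, length.out = n - 1), 3),
    aromaticity = seq(0.01, 0.2, length.out = n),
    net_charge = seq(-5, 5, length.out = n),
    cys_fraction = seq(0.01, 0.1, length.out = n),
    length = seq(100, 800, length.out = n),
    beta_fraction = seq(0.1, 0.5, length.out = n),
    mean_rsa = seq(0.3, 0.7, length.out = n),
    mean_disorder = seq(0.2, 0.6, length.out = n))
  rank_matrix(props)
}

screen_abundance <- function(ids, top = "hit") {
  tibble::tibble(
    protein_id = ids,
    approach = "supernatant",
    ibaq = ifelse(ids == top, 100, seq_along(ids)))
}

screen_secretion <- function(ids, secreted = ids) {
  tibble::tibble(protein_id = ids,
                 category = ifelse(ids %in% secreted, "SP", "None"),
                 secreted_or_extracellular = ids %in% secreted)
}

test_that("selection requires an extreme property, abundance and secretion", {
  rm_ <- screen_fixture()
  ab <- screen_abundance(rm_$protein_id)
  sec <- screen_secretion(rm_$protein_id, secreted = "hit")
  out <- select_candidates(rm_, ab, sec)
  expect_equal(out$protein_id, "hit")
  expect_true(out$trig_gravy)
  expect_equal(out$approaches, "supernatant")

  # same protein without secretion evidence is rejected
  sec_none <- screen_secretion(rm_$protein_id, secreted = character())
  expect_equal(nrow(select_candidates(rm_, ab, sec_none)), 0)

  # and with bottom-half abundance everywhere it is rejected too
  ab_low <- dplyr::mutate(ab, ibaq = ifelse(protein_id == "hit",
                                            0.01, ibaq))
  expect_equal(nrow(select_candidates(rm_, ab_low, sec)), 0)
})

test_that("charge triggers on absolute value, most negative included", {
  n <- 20
  props <- tibble::tibble(
    protein_id = sprintf("p%02d", seq_len(n)),
    gravy = seq(-1, 0, length.out = n),
    aromaticity = seq(0.01, 0.1, length.out = n),
    net_charge = c(-12, seq(-2, 2, length.out = n - 1)),
    cys_fraction = seq(0.01, 0.05, length.out = n),
    length = seq(100, 500, length.out = n),
    beta_fraction = seq(0.1, 0.3, length.out = n),
    mean_rsa = seq(0.4, 0.6, length.out = n),
    mean_disorder = seq(0.3, 0.5, length.out = n))
  rm_ <- rank_matrix(props)
  expect_equal(rm_$net_charge[[1]], 1 / n)      # lowest signed value
  expect_equal(rm_$net_charge_abs[[1]], 1)      # largest magnitude
  ab <- screen_abundance(props$protein_id, top = "p01")
  sec <- screen_secretion(props$protein_id)
  out <- select_candidates(rm_, ab, sec)
  expect_true("p01" %in% out$protein_id)
  expect_true(out$trig_net_charge_abs[out$protein_id == "p01"])
})

test_that("top-rule trigger counts respect the strict 10% boundary", {
  withr::local_seed(51)
  for (i in 1:10) {
    n <- sample(c(20, 50, 73, 100), 1)
    v <- sample(seq_len(1000), n)  # distinct values
    pct <- rank_percentiles(v)
    n_top <- sum(pct > 0.9)
    expect_gte(n_top, floor(0.1 * n))
    expect_lte(n_top, ceiling(0.1 * n))
    n_bottom <- sum(pct <= 0.1)
    expect_gte(n_bottom, floor(0.1 * n))
    expect_lte(n_bottom, ceiling(0.1 * n))
  }
})

test_that("two planted blobs in rank space are recovered at k = 2", {
  withr::local_seed(52)
  make_blob <- function(center, ids) {
    tibble::tibble(protein_id = ids) %>%
      dplyr::bind_cols(as.data.frame(matrix(
        pmin(pmax(center + runif(length(ids) * 8, -0.05, 0.05), 0), 1),
        ncol = 8, dimnames = list(NULL, secretome:::PROPERTY_NAMES))))
  }
  ranks <- dplyr::bind_rows(
    make_blob(0.1, sprintf("lo%02d", 1:6)),
    make_blob(0.9, sprintf("hi%02d", 1:6)))
  cands <- tibble::tibble(protein_id = ranks$protein_id)
  cl <- cluster_candidates(ranks, cands, k = 2)
  got <- cl$assignments
  lo <- got$cluster_id[startsWith(got$protein_id, "lo")]
  hi <- got$cluster_id[startsWith(got$protein_id, "hi")]
  expect_equal(length(unique(lo)), 1)
  expect_equal(length(unique(hi)), 1)
  expect_false(unique(lo) == unique(hi))
})

test_that("clustering is deterministic, order-invariant, and k = n gives singletons", {
  withr::local_seed(53)
  n <- 12
  ranks <- tibble::tibble(protein_id = sprintf("p%02d", seq_len(n))) %>%
    dplyr::bind_cols(as.data.frame(matrix(
      runif(n * 8), ncol = 8,
      dimnames = list(NULL, secretome:::PROPERTY_NAMES))))
  cands <- tibble::tibble(protein_id = ranks$protein_id)
  c1 <- cluster_candidates(ranks, cands, k = 3)
  c2 <- cluster_candidates(ranks[sample.int(n), ],
                           cands[sample.int(n), ], k = 3)
  expect_equal(c1$assignments, c2$assignments)

  singles <- cluster_candidates(ranks, cands, k = n)
  expect_equal(sort(unique(singles$assignments$cluster_id)), seq_len(n))
  expect_error(cluster_candidates(ranks, cands, k = n + 1), "smaller k")
})

test_that("duplicated profiles merge first and share a cluster", {
  withr::local_seed(54)
  n <- 8
  ranks <- tibble::tibble(protein_id = sprintf("p%02d", seq_len(n))) %>%
    dplyr::bind_cols(as.data.frame(matrix(
      runif(n * 8), ncol = 8,
      dimnames = list(NULL, secretome:::PROPERTY_NAMES))))
  ranks[8, -1] <- ranks[1, -1]  # duplicate of p01
  cands <- tibble::tibble(protein_id = ranks$protein_id)
  cl <- cluster_candidates(ranks, cands, k = 4)
  a <- cl$assignments
  expect_equal(a$cluster_id[a$protein_id == "p01"],
               a$cluster_id[a$protein_id == "p08"])
  expect_equal(min(cl$linkage$height), 0)
})

test_that("cluster ids are ordered by decreasing size", {
  withr::local_seed(55)
  ranks <- dplyr::bind_rows(
    tibble::tibble(protein_id = sprintf("a%02d", 1:7)) %>%
      dplyr::bind_cols(as.data.frame(matrix(
        0.1 + runif(7 * 8, 0, 0.04), ncol = 8,
        dimnames = list(NULL, secretome:::PROPERTY_NAMES)))),
    tibble::tibble(protein_id = sprintf("b%02d", 1:3)) %>%
      dplyr::bind_cols(as.data.frame(matrix(
        0.9 - runif(3 * 8, 0, 0.04), ncol = 8,
        dimnames = list(NULL, secretome:::PROPERTY_NAMES)))))
  cl <- cluster_candidates(ranks,
                           tibble::tibble(protein_id = ranks$protein_id),
                           k = 2)
  sizes <- table(cl$assignments$cluster_id)
  expect_equal(unname(sizes[["1"]]), 7)
  expect_equal(unname(sizes[["2"]]), 3)
})

test_that("cluster report shares are bounded by the candidate biomass", {
  rm_ <- screen_fixture(12)
  ids <- rm_$protein_id
  ab <- tibble::tibble(protein_id = rep(ids, 2),
                       approach = rep(c("whole", "shaved"), each = 12),
                       ibaq = rep(seq(1, 12), 2))
  sec <- screen_secretion(ids)
  cands <- tibble::tibble(protein_id = ids[1:6])
  cl <- cluster_candidates(rm_, cands, k = 2)
  rep_ <- cluster_report(cands, cl, ab, sec, rm_)
  expect_equal(nrow(rep_$summary), 2)
  expect_equal(sum(rep_$summary$n_members), 6)
  cand_share <- sum(ab$ibaq[ab$protein_id %in% cands$protein_id &
                              ab$approach == "whole"]) /
    sum(ab$ibaq[ab$approach == "whole"])
  expect_true(all(rep_$summary$share_whole <= cand_share + 1e-12))
  # heatmap rows follow the dendrogram order
  expect_equal(rep_$heatmap$protein_id, cl$order)
  # single-member cluster property means equal the member's percentiles
  one <- cluster_candidates(rm_, tibble::tibble(protein_id = ids[1:2]),
                            k = 2)
  r1 <- cluster_report(tibble::tibble(protein_id = ids[1:2]), one, ab,
                       sec, rm_)
  m <- r1$summary
  for (p in secretome:::PROPERTY_NAMES) {
    row <- rm_[rm_$protein_id == ids[[1]], ][[p]]
    cid <- one$assignments$cluster_id[one$assignments$protein_id ==
                                        ids[[1]]]
    expect_equal(m[[paste0("mean_", p)]][m$cluster_id == cid], row)
  }
})
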