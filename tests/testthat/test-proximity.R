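# Small annotated globule used across proximity tests.
globule_setup <- function(seed = 400, len = 150) {
  ch <- make_chimera(list(segment_spec("globule", len)), seed = seed,
                     protein_id = "G1")
  residues <- annotate_structure(ch$structure, ch$pae)
  list(structure = ch$structure, pae = ch$pae, residues = residues,
       structures = list(G1 = ch$structure), paes = list(G1 = ch$pae))
}

sites_at <- function(positions, residues, ptm_type = "p") {
  idx <- match(positions, residues$position)
  tibble::tibble(protein_id = residues$protein_id[idx], position = positions,
                 aa = residues$aa[idx], ptm_type = ptm_type,
                 regulatory = FALSE)
}

test_that("pae_distance adds the symmetrized PAE and rejects self-distances", {
  ca <- rbind(c(0, 0, 0), c(3, 0, 0))
  s <- toy_structure(ca)
  pae0 <- matrix(0, 2, 2)
  expect_equal(pae_distance(s, pae0, 1, 2), 3)
  pae <- matrix(c(0, 4, 2, 0), 2, 2)   # PAE[1,2]=2, PAE[2,1]=4 -> max 4
  expect_equal(pae_distance(s, pae, 1, 2), 7)
  expect_equal(pae_distance(s, pae, 2, 1), 7)   # symmetric by construction
  expect_gte(pae_distance(s, pae, 1, 2), 3)     # never below the CA distance
  expect_error(pae_distance(s, pae, 2, 2), "self")
})

test_that("with zero PAE the distance reduces to the Euclidean CA distance", {
  fx <- random_fixture(90, max_len = 60)
  n <- nrow(fx$structure)
  zero <- matrix(0, n, n)
  ca <- as.matrix(fx$structure[, c("ca_x", "ca_y", "ca_z")])
  pairs <- with_seed_local(91, cbind(sample(n, 20, TRUE), sample(n, 20, TRUE)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_equal(pae_distance(fx$structure, zero, i, j),
                 sqrt(sum((ca[i, ] - ca[j, ])^2)))
  }
})

test_that("two phosphosites 3 A apart land in the first self-proximity bin", {
  # two S residues close in space, a third far away
  ca <- rbind(c(0, 0, 0), c(3, 0, 0), c(40, 0, 0))
  s <- toy_structure(ca, aa = c("S", "S", "S"), protein_id = "T1")
  pae <- matrix(0, 3, 3)
  residues <- tibble::tibble(protein_id = "T1", position = 1:3, aa = "S",
                             idr = FALSE, short_idr = FALSE,
                             extended_short_idr = FALSE, exposure = "high",
                             eligible_proximity = TRUE)
  sites <- sites_at(1:2, residues)
  prof <- ptm_proximity(sites, residues, list(T1 = s), list(T1 = pae),
                        source_type = "p", n_randomizations = 2, seed = 1)
  first <- prof[prof$bin_lo == 1 & prof$bin_hi == 5, ]
  expect_equal(first$fraction_observed, 1)
  expect_equal(first$n_pairs, 2)       # each site sees the other
})

test_that("the colocalization zero bin captures same-residue competition", {
  ca <- rbind(c(0, 0, 0), c(20, 0, 0))
  s <- toy_structure(ca, aa = c("K", "K"), protein_id = "T1")
  pae <- matrix(0, 2, 2)
  residues <- tibble::tibble(protein_id = "T1", position = 1:2, aa = "K",
                             idr = FALSE, short_idr = FALSE,
                             extended_short_idr = FALSE, exposure = "high",
                             eligible_proximity = TRUE)
  sites <- dplyr::bind_rows(sites_at(1, residues, "ub"),
                            sites_at(1, residues, "ac"))
  prof <- ptm_proximity(sites, residues, list(T1 = s), list(T1 = pae),
                        source_type = "ub", target_type = "ac",
                        n_randomizations = 2, seed = 1)
  zero_bin <- prof[prof$bin_lo == 0 & prof$bin_hi == 1, ]
  expect_equal(zero_bin$n_pairs, 1)          # the source residue itself
  expect_equal(zero_bin$fraction_observed, 1)
})

test_that("profiles are seed-stable and randomization conserves counts", {
  gs <- globule_setup(401)
  acc <- gs$residues[gs$residues$aa %in% c("S", "T", "Y"), ]
  mods <- with_seed_local(402, acc[sample(nrow(acc), 8), ])
  sites <- sites_at(mods$position, gs$residues)
  p1 <- ptm_proximity(sites, gs$residues, gs$structures, gs$paes, "p",
                      n_randomizations = 4, seed = 9)
  p2 <- ptm_proximity(sites, gs$residues, gs$structures, gs$paes, "p",
                      n_randomizations = 4, seed = 9)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  # total pair count is conserved: observed and each randomization place
  # the same number of modifications, so n_pairs depends only on geometry
  expect_equal(sum(p1$n_modified <= p1$n_pairs), nrow(p1))
  p3 <- ptm_proximity(sites, gs$residues, gs$structures, gs$paes, "p",
                      n_randomizations = 4, seed = 10)
  expect_false(identical(p1$mean_random, p3$mean_random))
})

test_that("an empty site table yields an empty profile with a warning", {
  gs <- globule_setup(403, len = 60)
  sites <- sites_at(integer(0), gs$residues)
  expect_warning(
    prof <- ptm_proximity(sites, gs$residues, gs$structures, gs$paes, "p"),
    "no modified source")
  expect_true(all(prof$n_pairs == 0))
})

test_that("a planted 3D hotspot produces significant low-distance bins", {
  gs <- globule_setup(404, len = 200)
  prof0 <- compute_ppse(gs$structure, gs$pae)
  acc <- gs$residues$position[gs$residues$aa %in% c("S", "T", "Y")]
  center <- acc[which.min(abs(acc - 100))]
  # exposure_cutoff below any attainable count makes the hotspot the only
  # high-probability region: baseline p_buried everywhere else
  sites <- simulate_ptm_sites(gs$structure, prof0, "p",
                              p_modify_exposed = 0.9, p_modify_buried = 0.05,
                              exposure_cutoff = -1,
                              cluster_center = center, cluster_radius = 8,
                              seed = 405)
  prof <- ptm_proximity(sites, gs$residues, gs$structures, gs$paes, "p",
                        n_randomizations = 5, seed = 406)
  low <- prof[prof$bin_hi <= 10 & prof$n_pairs > 0, ]
  expect_true(any(low$fraction_observed >
                    low$mean_random + 1.96 * low$sd_random))
})

test_that("cluster test is degenerate when every acceptor is modified", {
  gs <- globule_setup(407, len = 80)
  acc <- gs$residues[gs$residues$aa %in% c("S", "T", "Y"), ]
  sites <- sites_at(acc$position, gs$residues)
  res <- ptm_cluster_test(sites, gs$residues, gs$structures, gs$paes, "p",
                          n_permutations = 200, seed = 1)
  expect_equal(res$empirical_p, 1)
})

test_that("proteins below min_sites are skipped and recorded", {
  gs <- globule_setup(408, len = 80)
  acc <- gs$residues[gs$residues$aa %in% c("S", "T", "Y"), ]
  sites <- sites_at(acc$position[1:2], gs$residues)
  res <- ptm_cluster_test(sites, gs$residues, gs$structures, gs$paes, "p",
                          n_permutations = 100, min_sites = 3, seed = 1)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "skipped"), "G1")
})

test_that("a tight pocket of sites gives a small, seed-stable empirical p", {
  gs <- globule_setup(409, len = 200)
  ca <- as.matrix(gs$structure[, c("ca_x", "ca_y", "ca_z")])
  acc <- gs$residues$position[gs$residues$aa %in% c("S", "T", "Y") &
                                gs$residues$eligible_proximity]
  center <- acc[which.min(abs(acc - 100))]
  d <- sqrt(colSums((t(ca[acc, ]) - ca[center, ])^2))
  pocket <- acc[order(d)][1:5]
  sites <- sites_at(pocket, gs$residues)
  r1 <- ptm_cluster_test(sites, gs$residues, gs$structures, gs$paes, "p",
                         n_permutations = 2000, seed = 11)
  expect_lte(r1$empirical_p, 0.01)
  r2 <- ptm_cluster_test(sites, gs$residues, gs$structures, gs$paes, "p",
                         n_permutations = 2000, seed = 11)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
})

test_that("empirical p tightens as a simulated cluster shrinks", {
  gs <- globule_setup(410, len = 200)
  ca <- as.matrix(gs$structure[, c("ca_x", "ca_y", "ca_z")])
  acc <- gs$residues$position[gs$residues$aa %in% c("S", "T", "Y") &
                                gs$residues$eligible_proximity]
  center <- acc[which.min(abs(acc - 100))]
  d <- sqrt(colSums((t(ca[acc, ]) - ca[center, ])^2))
  ps <- vapply(c(20, 12, 8), function(radius) {
    inside <- acc[d <= radius]
    take <- with_seed_local(12, sample(inside, min(5, length(inside))))
    sites <- sites_at(take, gs$residues)
    ptm_cluster_test(sites, gs$residues, gs$structures, gs$paes, "p",
                     n_permutations = 1000, min_sites = 3,
                     seed = 12)$empirical_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 1001 & ps <= 1))
})
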