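make_ptm_file <- function(rows, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], position = as.numeric(r[[2]]),
               aa = r[[3]], ptm_type = r[[4]],
               regulatory = isTRUE(r$regulatory))
  }))
  if (grepl("csv$", ext)) readr::write_csv(df, f) else readr::write_tsv(df, f)
  f
}

test_that("acceptor filtering drops residue/type mismatches and reports them", {
  f <- make_ptm_file(list(
    list("P1", 10, "K", "p"),        # K cannot be phosphorylated -> dropped
    list("P1", 11, "S", "p"),
    list("P1", 12, "K", "ub"),
    list("P1", 13, "R", "ub"),       # R cannot be ubiquitinated -> dropped
    list("P1", 14, "R", "m")))
  tab <- read_ptm_table(f)
  expect_equal(nrow(tab), 3)
  rep <- filter_report(tab)
  expect_equal(rep$p_rejected, 1L)
  expect_equal(rep$ub_rejected, 1L)
  expect_equal(rep$kept, 3L)
})

test_that("duplicate (protein, position, type) rows collapse to one", {
  f <- make_ptm_file(list(list("P1", 10, "K", "ub"),
                          list("P1", 10, "K", "ub"),
                          list("P1", 10, "K", "sm")))
  tab <- read_ptm_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(filter_report(tab)$duplicates_collapsed, 1L)
})

test_that("methylation subtypes are grouped into one m type", {
  f <- make_ptm_file(list(list("P1", 5, "K", "m1"),
                          list("P1", 7, "R", "m2"),
                          list("P1", 9, "K", "me")))
  tab <- read_ptm_table(f)
  expect_equal(unique(tab$ptm_type), "m")
  expect_equal(nrow(tab), 3)
})

test_that("regulatory sites missing from the main list are added there", {
  main <- make_ptm_file(list(list("P1", 10, "K", "ac")))
  reg <- make_ptm_file(list(list("P1", 12, "K", "ac"),
                            list("P1", 10, "K", "ac")))
  tab <- read_ptm_table(main, regulatory = reg)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$regulatory))
  expect_equal(filter_report(tab)$regulatory_added, 1L)
})

test_that("malformed positions are a hard error and order does not matter", {
  f <- make_ptm_file(list(list("P1", 0, "S", "p")))
  expect_error(read_ptm_table(f), "malformed")
  f2 <- make_ptm_file(list(list("P1", 2.5, "S", "p")))
  expect_error(read_ptm_table(f2), "malformed")
  rows <- list(list("P1", 11, "S", "p"), list("P1", 3, "Y", "p"),
               list("P2", 8, "K", "ub"), list("P1", 10, "K", "p"))
  t1 <- read_ptm_table(make_ptm_file(rows))
  t2 <- read_ptm_table(make_ptm_file(rev(rows)))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("CSV input is accepted alongside TSV", {
  f <- make_ptm_file(list(list("P1", 11, "S", "p")), ext = ".csv")
  expect_equal(nrow(read_ptm_table(f)), 1)
})

test_that("annotation joins structure context and applies the eligibility rule", {
  pro <- chimera_proteome(n_proteins = 1, seed = 200, coil_len = 40)
  res <- pro$residues
  idr_pos <- res$position[res$idr & res$aa %in% c("S", "T", "Y")]
  str_pos <- res$position[!res$idr & res$aa %in% c("S", "T", "Y")]
  ptm <- tibble::tibble(
    protein_id = c("PROT1", "PROT1", "PROT1", "UNKNOWN"),
    position = c(str_pos[1], idr_pos[1], 9999, 5),
    aa = c(res$aa[res$position == str_pos[1]],
           res$aa[res$position == idr_pos[1]], "S", "S"),
    ptm_type = "p", regulatory = FALSE)
  expect_warning(ann <- annotate_ptm_sites(ptm, res), "without structure")
  expect_equal(nrow(ann), 2)   # out-of-bounds and unknown protein dropped
  rep <- attr(ann, "mismatch_report")
  expect_equal(rep$unknown_protein, 1L)
  expect_equal(rep$sequence_mismatch, 1L)
  expect_equal(rep$input - rep$unknown_protein - rep$sequence_mismatch, rep$kept)
  # long-IDR site ineligible for proximity, structured site eligible
  expect_true(ann$eligible_proximity[ann$position == str_pos[1]])
  expect_false(ann$eligible_proximity[ann$position == idr_pos[1]])
  expect_error(annotate_ptm_sites(ptm, res, on_unknown = "error"), "structure")
})

test_that("a site inside a short IDR stays proximity-eligible", {
  pro <- chimera_proteome(n_proteins = 1, seed = 205, coil_len = 15)
  res <- pro$residues
  short_acc <- res[res$short_idr & res$aa %in% c("S", "T", "Y"), ]
  expect_gt(nrow(short_acc), 0)
  ptm <- tibble::tibble(protein_id = short_acc$protein_id[1],
                        position = short_acc$position[1],
                        aa = short_acc$aa[1], ptm_type = "p", regulatory = FALSE)
  ann <- annotate_ptm_sites(ptm, res)
  expect_true(ann$eligible_proximity[1])
})

test_that("sequence windows pad with underscores at the termini", {
  expect_equal(extract_window("MKSTR", 3), "____MKSTR____")
  expect_equal(substr(extract_window("MKSTRLLQWE", 1), 1, 6), "______")
  expect_equal(extract_window("MKSTR", 5, k = 2), "STR__")
  # central character always matches the sequence
  s <- "ACDEFGHIKLMNPQRSTVWY"
  for (p in c(1, 7, 20)) {
    expect_equal(substr(extract_window(s, p), 7, 7), substr(s, p, p))
  }
  # acceptor validation drops non-phosphoacceptor centers
  w <- extract_window("MKSTR", c(2, 3), central = c("S", "T", "Y"))
  expect_true(is.na(w[1]))
  expect_false(is.na(w[2]))
})

test_that("motif matching anchors the marked center and reports overlaps", {
  occ <- match_motifs(c(P1 = "ARTRQASFA"),
                      data.frame(name = "rxrxxsf", pattern = "R.R..([ST])F"))
  expect_equal(occ$position, 7L)
  # no acceptor anywhere -> empty
  empty <- match_motifs(c(P1 = "AAAAAA"),
                        data.frame(name = "s", pattern = "([S])"))
  expect_equal(nrow(empty), 0)
  # overlapping occurrences are all reported
  occ2 <- match_motifs(c(P1 = "SSSS"),
                       data.frame(name = "ss", pattern = "([S])S"))
  expect_equal(occ2$position, 1:3)
  # wildcard motif matches every interior position of a 13-mer context
  occ3 <- match_motifs(c(P1 = strrep("A", 20)),
                       data.frame(name = "any", pattern = "......(.)......"))
  expect_equal(occ3$position, 7:14)
})

test_that("motif patterns without exactly one capture group are rejected at load", {
  expect_error(read_motifs(data.frame(name = "bad", pattern = "RRS")),
               "capture group")
  expect_error(read_motifs(data.frame(name = "bad2", pattern = "(R)(S)")),
               "capture group")
  expect_error(read_motifs(data.frame(name = "broken", pattern = "([S)")))
  expect_silent(read_motifs(data.frame(name = "ok", pattern = "R.R..([ST])F")))
})

test_that("PSSM log-odds scores follow the closed form", {
  # single window, uniform background, vanishing pseudocount
  pssm <- build_pssm("AAA", pseudocount = 1e-12)
  expect_equal(pssm["A", "0"], log2(20), tolerance = 1e-6)
  # all-padding columns carry zero evidence
  pssm2 <- build_pssm(c("_A_", "_A_"))
  expect_equal(unname(pssm2[, "-1"]), rep(0, 20))
  expect_equal(unname(pssm2[, "1"]), rep(0, 20))
  # background must sum to one
  bad_bg <- stats::setNames(rep(0.06, 20), structptm:::AA1)
  expect_error(build_pssm("AAA", background = bad_bg), "sum to 1")
  # score_window sums per-column scores, padding scoring zero
  expect_equal(score_window(pssm2, "_A_"), pssm2["A", "0"])
})

test_that("PSSM of background-sampled windows shrinks toward zero with N", {
  stats_at <- function(n) {
    wins <- with_seed_local(n, vapply(seq_len(n), function(i) {
      paste(sample(structptm:::AA1, 5, replace = TRUE), collapse = "")
    }, character(1)))
    m <- build_pssm(wins)
    c(max = max(abs(m)), col_mean = max(colMeans(abs(m))))
  }
  res <- vapply(c(100, 1000, 10000), stats_at, numeric(2))
  expect_true(all(diff(res["max", ]) < 0))       # slope check over N
  expect_lt(res["col_mean", 3], 0.1)             # per-column shrinkage
})

test_that("exposure split partitions sites and draws a matched subset", {
  ann <- tibble::tibble(protein_id = "P1", position = 1:140,
                        aa = "S", ptm_type = "p",
                        ppse = c(rep(2L, 100), rep(9L, 40)))
  sp <- split_by_exposure(ann, seed = 5)
  expect_equal(nrow(sp$high), 100)
  expect_equal(nrow(sp$low), 40)
  expect_equal(nrow(sp$matched), 40)
  expect_true(all(sp$matched$position %in% sp$high$position))
  sp2 <- split_by_exposure(ann, seed = 5)
  expect_identical(sp$matched, sp2$matched)          # seeded determinism
  # degenerate splits
  all_high <- split_by_exposure(dplyr::mutate(ann, ppse = 1L))
  expect_equal(nrow(all_high$low), 0)
  expect_equal(nrow(all_high$matched), 0)
  flipped <- ann
  flipped$ppse <- rev(flipped$ppse)
  small_high <- flipped[1:60, ]   # 20 high, 40 low
  expect_warning(sp3 <- split_by_exposure(small_high), "entire high set")
  expect_equal(nrow(sp3$matched), nrow(sp3$high))
})
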