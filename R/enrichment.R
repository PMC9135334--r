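#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric implementation: conditional on the table margins,
#' the p-value sums the probabilities of every table whose probability does
#' not exceed that of the observed table (with a relative tolerance factor
#' of `1 + 1e-7` on the comparison, the convention of the common reference
#' implementations). The odds ratio is the sample odds ratio `(a d)/(b c)`,
#' reported as `Inf` when `b c = 0` with `a d > 0` and `NaN` for `0/0`.
#'
#' @param a,b,c,d Cell counts: `a` = in-category & modified, `b` =
#'   in-category & unmodified, `c` = out-category & modified, `d` =
#'   out-category & unmodified.
#' @return List with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_two_sided(5, 0, 0, 5)
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table must have at least one observation", call. = FALSE)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  support <- max(0, col1 - row2):min(col1, row1)
  dens <- stats::dhyper(support, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control:
#' `adj_i = min_{j : rank_j >= rank_i} (m p_j / rank_j)`, capped at 1; the
#' sort is stable so ties keep input order.
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @return Adjusted p-values, in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Build and test one 2x2 enrichment table over a residue universe.
enrich_table <- function(universe, in_flag, modified, design, ptm_type) {
  if (nrow(universe) == 0) {
    stop("empty residue universe for design '", design, "'", call. = FALSE)
  }
  a <- sum(in_flag & modified)
  b <- sum(in_flag & !modified)
  cc <- sum(!in_flag & modified)
  dd <- sum(!in_flag & !modified)
  ft <- fisher_two_sided(a, b, cc, dd)
  tibble::tibble(design = design, ptm_type = ptm_type,
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 adj_p_value = NA_real_, n_sites = a + cc,
                 a = a, b = b, c = cc, d = dd)
}

# Resolve universe + in-category flag for one enrichment design.
design_universe <- function(residues, ptm_type, design, acceptor_map,
                            motif_occurrences = NULL) {
  acc <- residues[residues$aa %in% acceptor_map[[ptm_type]], ]
  key <- function(tab) paste(tab$protein_id, tab$position)
  in_motif <- function(tab) {
    if (is.null(motif_occurrences)) {
      stop("design requires motif_occurrences", call. = FALSE)
    }
    key(tab) %in% key(motif_occurrences)
  }
  switch(design,
    idr = list(universe = acc, in_flag = acc$idr),
    short_idr_vs_all_idr = {
      u <- acc[acc$idr, ]
      list(universe = u, in_flag = u$short_idr)
    },
    exposure_high_in_structured = {
      u <- acc[!acc$idr, ]
      list(universe = u, in_flag = u$exposure == "high")
    },
    motif = list(universe = acc, in_flag = in_motif(acc)),
    motif_in_idr = {
      u <- acc[in_motif(acc), ]
      list(universe = u, in_flag = u$idr)
    },
    stop("unknown design: ", design, call. = FALSE))
}

#' Structural enrichment of PTM sites (one PTM type)
#'
#' Tests whether modified acceptor residues are over- or under-represented
#' in a structural category, using all acceptor residues of the PTM type
#' across the supplied proteome as the universe. Designs:
#' * `"idr"` - modification in disordered vs structured residues;
#' * `"short_idr_vs_all_idr"` - inside short IDRs vs all other IDR
#'   residues;
#' * `"exposure_high_in_structured"` - high vs low side-chain exposure,
#'   structured residues only;
#' * `"motif"` - inside motif occurrences vs all acceptors;
#' * `"motif_in_idr"` - among motif occurrences, disordered vs structured.
#'
#' @param sites Annotated site tibble ([annotate_ptm_sites()]).
#' @param residues Residue annotation tibble ([annotate_proteome()]).
#' @param ptm_type PTM type tested.
#' @param design One of the designs above.
#' @param acceptor_map See [ptm_acceptor_map()].
#' @param motif_occurrences Occurrence tibble from [match_motifs()] (motif
#'   designs only).
#' @param regulatory_only Restrict the modified set to regulatory sites.
#' @return One-row `structptm_enrichment` tibble: design, ptm_type,
#'   odds_ratio, p_value, adj_p_value, n_sites and the 2x2 cells.
#' @export
enrich_in_region <- function(sites, residues, ptm_type,
                             design = c("idr", "short_idr_vs_all_idr",
                                        "exposure_high_in_structured",
                                        "motif", "motif_in_idr"),
                             acceptor_map = ptm_acceptor_map(),
                             motif_occurrences = NULL,
                             regulatory_only = FALSE) {
  design <- match.arg(design)
  du <- design_universe(residues, ptm_type, design, acceptor_map,
                        motif_occurrences)
  mod_sites <- sites[sites$ptm_type == ptm_type, ]
  if (regulatory_only) mod_sites <- mod_sites[mod_sites$regulatory, ]
  modified <- paste(du$universe$protein_id, du$universe$position) %in%
    paste(mod_sites$protein_id, mod_sites$position)
  out <- enrich_table(du$universe, du$in_flag, modified, design, ptm_type)
  out$adj_p_value <- out$p_value
  class(out) <- unique(c("structptm_enrichment", class(out)))
  out
}

#' Enrichment across a family of PTM types with BH correction
#'
#' Runs [enrich_in_region()] for each PTM type and adjusts the p-values
#' across the family with [bh_adjust()] (one family per analysis design,
#' mirroring figure-level correction).
#'
#' @inheritParams enrich_in_region
#' @param ptm_types Types to test; defaults to every type present in
#'   `sites`.
#' @return `structptm_enrichment` tibble, one row per type.
#' @export
enrich_ptms <- function(sites, residues, ptm_types = NULL, design = "idr",
                        acceptor_map = ptm_acceptor_map(),
                        motif_occurrences = NULL, regulatory_only = FALSE) {
  ptm_types <- ptm_types %||% sort(unique(sites$ptm_type))
  out <- dplyr::bind_rows(lapply(ptm_types, function(ty) {
    enrich_in_region(sites, residues, ty, design, acceptor_map,
                     motif_occurrences, regulatory_only)
  }))
  out$adj_p_value <- bh_adjust(out$p_value)
  class(out) <- unique(c("structptm_enrichment", class(out)))
  out
}

#' Per-protein enrichment scan
#'
#' One 2x2 table per protein (structural category x modified) over that
#' protein's acceptor residues, BH-adjusted across all tested proteins.
#' Proteins without any modified acceptor, or whose universe degenerates
#' (all residues in one category), are skipped and counted in the
#' `skipped` attribute.
#'
#' @inheritParams enrich_in_region
#' @param min_modified Minimum modified acceptors for a protein to be
#'   tested.
#' @return `structptm_enrichment` tibble with a `protein_id` column.
#' @export
enrich_per_protein <- function(sites, residues, ptm_type, design = "idr",
                               acceptor_map = ptm_acceptor_map(),
                               min_modified = 1) {
  ids <- unique(residues$protein_id)
  skipped <- 0L
  rows <- list()
  for (id in ids) {
    res_i <- residues[residues$protein_id == id, ]
    du <- tryCatch(design_universe(res_i, ptm_type, design, acceptor_map),
                   error = function(e) NULL)
    if (is.null(du) || nrow(du$universe) == 0) {
      skipped <- skipped + 1L
      next
    }
    mod_sites <- sites[sites$ptm_type == ptm_type & sites$protein_id == id, ]
    modified <- du$universe$position %in% mod_sites$position
    if (sum(modified) < min_modified) {
      skipped <- skipped + 1L
      next
    }
    r <- enrich_table(du$universe, du$in_flag, modified, design, ptm_type)
    r$protein_id <- id
    rows[[length(rows) + 1]] <- r
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$adj_p_value <- bh_adjust(out$p_value)
    out <- dplyr::select(out, "protein_id", dplyr::everything())
  }
  attr(out, "skipped") <- skipped
  class(out) <- unique(c("structptm_enrichment", class(out)))
  out
}

#' @method tidy structptm_enrichment
#' @export
tidy.structptm_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance structptm_enrichment
#' @export
glance.structptm_enrichment <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_tests = nrow(x),
                 n_significant = sum(x$adj_p_value <= alpha, na.rm = TRUE),
                 min_adj_p = suppressWarnings(min(x$adj_p_value, na.rm = TRUE)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
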