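#' PAE-aware 3D distance between two residues
#'
#' The Euclidean CA-CA distance inflated by the symmetrized predicted
#' aligned error, `max(PAE[i,j], PAE[j,i])`, so that distances across
#' uncertainly positioned domains are counted conservatively. The distance
#' of a residue to itself is excluded by construction (an error), not zero.
#'
#' @param structure An `af_structure` tibble.
#' @param pae PAE matrix.
#' @param i,j 1-based residue positions, `i != j`.
#' @return Distance in Angstrom.
#' @export
pae_distance <- function(structure, pae, i, j) {
  if (any(i == j)) stop("distance to self is excluded (i must differ from j)",
                        call. = FALSE)
  ca <- ca_matrix(structure)
  sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2)) +
    pmax(pae[cbind(i, j)], pae[cbind(j, i)])
}

# Full PAE-aware distance matrix (diagonal 0).
pae_distance_matrix <- function(structure, pae) {
  d <- as.matrix(stats::dist(ca_matrix(structure))) + pmax(pae, t(pae))
  diag(d) <- 0
  unname(d)
}

proximity_bins <- function(mode = c("self", "colocalization")) {
  mode <- match.arg(mode)
  if (mode == "self") c(1, 5, 10, 15, 20, 25, 30, 35) else
    c(0, 1, 5, 10, 15, 20, 25, 30, 35)
}

# Count pairs and modified pairs per distance bin for one protein.
# src: source positions (modified); tgt: eligible target acceptor
# positions; tgt_mod: logical modified flag aligned with tgt.
bin_pairs <- function(dmat, src, tgt, tgt_mod, edges, self) {
  nb <- length(edges) - 1
  tot <- numeric(nb)
  mod <- numeric(nb)
  for (s in src) {
    keep <- if (self) tgt != s else rep(TRUE, length(tgt))
    d <- dmat[s, tgt[keep]]
    bin <- cut(d, breaks = edges, right = TRUE, include.lowest = edges[1] == 0,
               labels = FALSE)
    ok <- !is.na(bin)
    tot <- tot + tabulate(bin[ok], nb)
    mm <- tgt_mod[keep][ok]
    mod <- mod + tabulate(bin[ok][mm], nb)
  }
  list(total = tot, modified = mod)
}

#' Global binned 3D co-modification profile
#'
#' For every modified source-type residue, every eligible target-type
#' acceptor in the same protein is assigned to the distance bin of its
#' PAE-aware 3D distance, and the fraction of those acceptors that are
#' themselves modified is compared per bin against randomized backgrounds
#' in which each protein's target modifications are redistributed uniformly
#' over its eligible acceptors. Self-proximity (`source_type ==
#' target_type`) excludes the source residue itself and starts binning at
#' 1 Angstrom; colocalization profiles start at 0 Angstrom so that
#' competition for the identical residue is visible in the leading bin.
#' Only structured and short-IDR residues are used when `eligible_only`
#' (long disordered regions are removed).
#'
#' @param sites Annotated site tibble ([annotate_ptm_sites()]).
#' @param residues Residue annotation tibble.
#' @param structures,paes Named lists keyed by protein id.
#' @param source_type,target_type PTM types (equal for self-proximity).
#' @param bin_edges Ascending bin edges in Angstrom; defaults depend on the
#'   mode.
#' @param n_randomizations Number of randomized backgrounds (>= 1).
#' @param seed Integer seed for the randomizations.
#' @param eligible_only Restrict to proximity-eligible residues.
#' @param acceptor_map See [ptm_acceptor_map()].
#' @return A `structptm_proximity` tibble with one row per bin:
#'   `bin_lo`, `bin_hi`, `n_pairs`, `n_modified`, `fraction_observed`,
#'   `mean_random`, `sd_random`, `z`, `significant` (`|z| >= 1.96` with
#'   positive sd).
#' @export
ptm_proximity <- function(sites, residues, structures, paes,
                          source_type, target_type = source_type,
                          bin_edges = NULL, n_randomizations = 5, seed = 1,
                          eligible_only = TRUE,
                          acceptor_map = ptm_acceptor_map()) {
  stopifnot(n_randomizations >= 1)
  self <- source_type == target_type
  edges <- bin_edges %||% proximity_bins(if (self) "self" else "colocalization")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly ascending", call. = FALSE)
  }
  nb <- length(edges) - 1

  # per-protein eligible acceptors and modification flags
  per_protein <- list()
  for (id in unique(residues$protein_id)) {
    res_i <- residues[residues$protein_id == id, ]
    if (eligible_only) res_i <- res_i[res_i$eligible_proximity, ]
    tgt <- res_i$position[res_i$aa %in% acceptor_map[[target_type]]]
    src_univ <- res_i$position[res_i$aa %in% acceptor_map[[source_type]]]
    s_i <- sites[sites$protein_id == id, ]
    src <- intersect(s_i$position[s_i$ptm_type == source_type], src_univ)
    tgt_mod_pos <- intersect(s_i$position[s_i$ptm_type == target_type], tgt)
    if (length(src) == 0 || length(tgt) == 0) next
    per_protein[[id]] <- list(
      dmat = pae_distance_matrix(structures[[id]], paes[[id]]),
      src = src, tgt = tgt, src_univ = src_univ,
      tgt_mod = tgt %in% tgt_mod_pos)
  }
  empty_profile <- function() {
    tibble::tibble(source = source_type, target = target_type,
                   bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                   n_pairs = 0, n_modified = 0,
                   fraction_observed = NA_real_, mean_random = NA_real_,
                   sd_random = NA_real_, z = NA_real_, significant = FALSE)
  }
  if (length(per_protein) == 0) {
    warning("no modified source residues; empty profile", call. = FALSE)
    out <- empty_profile()
    class(out) <- unique(c("structptm_proximity", class(out)))
    return(out)
  }

  profile_fraction <- function(get_src, get_tgt_mod) {
    tot <- numeric(nb)
    mod <- numeric(nb)
    for (pp in per_protein) {
      bp <- bin_pairs(pp$dmat, get_src(pp), pp$tgt, get_tgt_mod(pp), edges, self)
      tot <- tot + bp$total
      mod <- mod + bp$modified
    }
    list(total = tot, modified = mod,
         fraction = ifelse(tot > 0, mod / tot, NA_real_))
  }
  obs <- profile_fraction(function(pp) pp$src, function(pp) pp$tgt_mod)

  rand_fracs <- matrix(NA_real_, n_randomizations, nb)
  for (r in seq_len(n_randomizations)) {
    rp <- with_private_seed(derive_seed(seed, r), {
      lapply(per_protein, function(pp) {
        k <- sum(pp$tgt_mod)
        new_mod_pos <- pp$tgt[sample(length(pp$tgt), k)]
        new_tgt_mod <- pp$tgt %in% new_mod_pos
        # for self-proximity the randomized set is both source and target
        new_src <- if (self) intersect(new_mod_pos, pp$src_univ) else pp$src
        list(dmat = pp$dmat, src = new_src, tgt = pp$tgt,
             src_univ = pp$src_univ, tgt_mod = new_tgt_mod)
      })
    })
    tot <- numeric(nb)
    mod <- numeric(nb)
    for (pp in rp) {
      if (length(pp$src) == 0) next
      bp <- bin_pairs(pp$dmat, pp$src, pp$tgt, pp$tgt_mod, edges, self)
      tot <- tot + bp$total
      mod <- mod + bp$modified
    }
    rand_fracs[r, ] <- ifelse(tot > 0, mod / tot, NA_real_)
  }
  mean_random <- colMeans(rand_fracs, na.rm = TRUE)
  sd_random <- apply(rand_fracs, 2, stats::sd, na.rm = TRUE)
  z <- ifelse(sd_random > 0, (obs$fraction - mean_random) / sd_random, NA_real_)
  out <- tibble::tibble(
    source = source_type, target = target_type,
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    n_pairs = obs$total, n_modified = obs$modified,
    fraction_observed = obs$fraction,
    mean_random = mean_random, sd_random = sd_random, z = z,
    significant = !is.na(z) & abs(z) >= 1.96 & sd_random > 0)
  attr(out, "n_randomizations") <- n_randomizations
  attr(out, "seed") <- seed
  class(out) <- unique(c("structptm_proximity", class(out)))
  out
}

#' Per-protein 3D PTM cluster permutation test
#'
#' For each protein with at least `min_sites` modified eligible acceptors,
#' the observed mean pairwise PAE-aware distance between the modified
#' residues is compared with the means of random draws of the same number
#' of residues from the protein's eligible acceptors (without
#' replacement). The empirical p-value uses the add-one estimator
#' `(1 + #{null <= observed}) / (1 + n_permutations)`, so it is never zero,
#' and is BH-adjusted across all tested proteins.
#'
#' @inheritParams ptm_proximity
#' @param ptm_type PTM type tested.
#' @param n_permutations Random draws per protein.
#' @param min_sites Minimum modified eligible acceptors.
#' @return A `structptm_cluster` tibble: `protein_id`, `ptm_type`,
#'   `n_sites`, `n_acceptors`, `observed_mean_distance`, `empirical_p`,
#'   `adj_p`; proteins skipped for too few sites are counted in the
#'   `skipped` attribute.
#' @export
ptm_cluster_test <- function(sites, residues, structures, paes, ptm_type,
                             n_permutations = 10000, min_sites = 3, seed = 1,
                             eligible_only = TRUE,
                             acceptor_map = ptm_acceptor_map()) {
  rows <- list()
  skipped <- character(0)
  ids <- unique(residues$protein_id)
  for (idx in seq_along(ids)) {
    id <- ids[idx]
    res_i <- residues[residues$protein_id == id, ]
    if (eligible_only) res_i <- res_i[res_i$eligible_proximity, ]
    acc <- res_i$position[res_i$aa %in% acceptor_map[[ptm_type]]]
    s_i <- sites[sites$protein_id == id & sites$ptm_type == ptm_type, ]
    mod <- intersect(s_i$position, acc)
    k <- length(mod)
    if (k < min_sites) {
      skipped <- c(skipped, id)
      next
    }
    dmat <- pae_distance_matrix(structures[[id]], paes[[id]])
    sub <- dmat[acc, acc, drop = FALSE]
    m <- length(acc)
    mod_idx <- match(mod, acc)
    pair_mean <- function(ii) sum(sub[ii, ii]) / (length(ii) * (length(ii) - 1))
    observed <- pair_mean(mod_idx)
    null_means <- with_private_seed(derive_seed(seed, idx), {
      vapply(seq_len(n_permutations),
             function(r) pair_mean(sample.int(m, k)), numeric(1))
    })
    p <- (1 + sum(null_means <= observed)) / (1 + n_permutations)
    rows[[length(rows) + 1]] <- tibble::tibble(
      protein_id = id, ptm_type = ptm_type, n_sites = k, n_acceptors = m,
      observed_mean_distance = observed, empirical_p = p, adj_p = NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$adj_p <- bh_adjust(out$empirical_p)
  attr(out, "skipped") <- skipped
  attr(out, "n_permutations") <- n_permutations
  class(out) <- unique(c("structptm_cluster", class(out)))
  out
}

#' @method tidy structptm_proximity
#' @export
tidy.structptm_proximity <- function(x, ...) tibble::as_tibble(x)

#' @method tidy structptm_cluster
#' @export
tidy.structptm_cluster <- function(x, ...) tibble::as_tibble(x)

#' @method glance structptm_cluster
#' @export
glance.structptm_cluster <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_proteins = nrow(x),
                 n_significant = sum(x$adj_p <= alpha, na.rm = TRUE),
                 n_skipped = length(attr(x, "skipped")))
}
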