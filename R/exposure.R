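#' @title Prediction-aware part-sphere exposure (pPSE)
#'
#' @description
#' For each residue i, pPSE counts the alpha carbons of other residues that
#' fall inside a cone of half-angle `angle` around the side-chain direction
#' (CB minus CA; ideal-tetrahedral pseudo-CB for glycine) and within
#' `radius` Angstrom of CA_i. When `use_pae` is true the distance between a
#' pair is inflated by the symmetrized predicted aligned error,
#' `max(PAE[i,j], PAE[j,i])`, so a neighbour counts only if it stays inside
#' the radius after adding its positional uncertainty. Low counts mean high
#' solvent exposure. The defaults (12 Angstrom, 70 degrees) are tuned for
#' side-chain exposure; a 24 Angstrom full sphere (angle 180) feeds the IDR
#' caller.
#'
#' @param structure An `af_structure` tibble.
#' @param pae PAE matrix (required when `use_pae = TRUE`).
#' @param radius Neighbourhood radius in Angstrom (> 0).
#' @param angle Cone half-angle in degrees, in (0, 180]; 180 is the full
#'   sphere and makes the result independent of side-chain direction.
#' @param use_pae Inflate pairwise distances by the symmetrized PAE.
#' @return A tibble of class `ppse_profile`: `protein_id`, `position`, `aa`,
#'   `ppse` (raw integer counts), with the configuration in attributes.
#' @export
#' @examples
#' chim <- make_chimera(list(segment_spec("helix", 30)), seed = 1)
#' prof <- compute_ppse(chim$structure, chim$pae)
#' head(prof)
compute_ppse <- function(structure, pae = NULL, radius = 12, angle = 70,
                         use_pae = TRUE) {
  stopifnot(radius > 0, angle > 0, angle <= 180)
  n <- nrow(structure)
  if (use_pae) {
    if (is.null(pae)) {
      stop("use_pae = TRUE but no PAE matrix supplied", call. = FALSE)
    }
    pae <- validate_pae(pae, n = n)
  }
  ca <- ca_matrix(structure)
  u <- side_chain_directions(structure)
  raw <- integer(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(ca))
    eff <- if (use_pae) d + pmax(pae, t(pae)) else d
    # small slack keeps exactly-on-cone neighbours inside the inclusive
    # boundary despite cos() rounding (e.g. cos(90 deg) != 0 in doubles)
    cos_cut <- cos(angle * pi / 180) - 1e-12
    for (i in seq_len(n)) {
      diff <- sweep(ca, 2, ca[i, ], `-`)
      cosv <- as.numeric(diff %*% u[i, ]) / d[i, ]
      ok <- eff[i, ] <= radius & cosv >= cos_cut
      ok[i] <- FALSE
      raw[i] <- sum(ok, na.rm = TRUE)
    }
  }
  out <- tibble::tibble(protein_id = structure$protein_id,
                        position = structure$position,
                        aa = structure$aa, ppse = raw)
  attr(out, "radius") <- radius
  attr(out, "angle") <- angle
  attr(out, "use_pae") <- use_pae
  class(out) <- c("ppse_profile", class(out))
  out
}

# Unit side-chain direction per residue; pseudo-CB from N/CA/C where CB is
# absent (glycine), following standard half-sphere-exposure practice.
side_chain_directions <- function(structure) {
  n <- nrow(structure)
  ca <- ca_matrix(structure)
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    cb <- c(structure$cb_x[i], structure$cb_y[i], structure$cb_z[i])
    if (any(is.na(cb))) {
      cb <- pseudo_cb(c(structure$n_x[i], structure$n_y[i], structure$n_z[i]),
                      ca[i, ],
                      c(structure$c_x[i], structure$c_y[i], structure$c_z[i]))
    }
    u[i, ] <- vunit(cb - ca[i, ])
  }
  u
}

# Ideal tetrahedral CB from backbone N, CA, C (the standard virtual-CB
# construction).
pseudo_cb <- function(n_xyz, ca_xyz, c_xyz) {
  b <- ca_xyz - n_xyz
  c2 <- c_xyz - ca_xyz
  a <- vcross(b, c2)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c2 + ca_xyz
}

#' Smooth a pPSE profile along the sequence
#'
#' Sliding-window average: position i is averaged over
#' `[i - half_window, i + half_window]` intersected with the sequence, i.e.
#' the window is truncated at the termini. The raw profile is retained.
#'
#' @param profile A `ppse_profile` tibble (or any tibble with a `ppse`
#'   column).
#' @param half_window Positive integer half-window (in residues).
#' @return The profile with an added `ppse_smooth` column.
#' @export
smooth_ppse <- function(profile, half_window = 10) {
  half_window <- as.integer(half_window)
  stopifnot(half_window >= 1)
  sm <- unlist(lapply(split(profile$ppse, profile$protein_id)[
    unique(profile$protein_id)], running_mean, w = half_window),
    use.names = FALSE)
  profile$ppse_smooth <- sm
  attr(profile, "half_window") <- half_window
  profile
}

running_mean <- function(x, w) {
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - w)
  hi <- pmin(n, idx + w)
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' IDR calling configuration
#'
#' Defaults reproduce the structure-based IDR caller: full-sphere pPSE at
#' 24 Angstrom with PAE, smoothed with a half-window of 10 residues, and a
#' disorder call at smoothed pPSE <= 34.27.
#'
#' @param radius,angle,use_pae Exposure configuration for the IDR score.
#' @param half_window Smoothing half-window (residues).
#' @param threshold Disorder call threshold on the smoothed score
#'   (inclusive).
#' @return A named list of class `idr_config`.
#' @export
idr_config <- function(radius = 24, angle = 180, use_pae = TRUE,
                       half_window = 10, threshold = 34.27) {
  stopifnot(radius > 0, threshold > 0, half_window >= 1)
  structure(list(radius = radius, angle = angle, use_pae = use_pae,
                 half_window = as.integer(half_window), threshold = threshold),
            class = "idr_config")
}

#' Call intrinsically disordered regions from a predicted structure
#'
#' Computes the full-sphere PAE-aware exposure, smooths it along the
#' sequence, and flags residues whose smoothed exposure falls at or below
#' the threshold: residues in disordered regions have few confidently
#' placed neighbours even in a large sphere.
#'
#' @param structure An `af_structure` tibble.
#' @param pae PAE matrix.
#' @param config An [idr_config()].
#' @return A tibble: `protein_id`, `position`, `aa`, `ppse_full` (raw),
#'   `ppse_smooth`, `idr` (logical).
#' @export
call_idr <- function(structure, pae, config = idr_config()) {
  prof <- compute_ppse(structure, pae, radius = config$radius,
                       angle = config$angle, use_pae = config$use_pae)
  prof <- smooth_ppse(prof, config$half_window)
  tibble::tibble(protein_id = prof$protein_id, position = prof$position,
                 aa = prof$aa, ppse_full = prof$ppse,
                 ppse_smooth = prof$ppse_smooth,
                 idr = prof$ppse_smooth <= config$threshold)
}

#' Short-IDR definition
#'
#' A short IDR is a maximal disordered run of at most `max_idr_len` residues
#' sandwiched between two structured runs of at least `min_flank_len`
#' residues each; such linkers between large folded domains are enriched in
#' regulatory modification sites. Each short IDR is also reported widened by
#' `extension` residues on either side (clipped to the sequence).
#'
#' @param max_idr_len Maximum disordered run length (residues).
#' @param min_flank_len Minimum structured flank length on both sides.
#' @param extension Widening applied to each side for the extended regions.
#' @return A named list of class `short_idr_config`.
#' @export
short_idr_config <- function(max_idr_len = 20, min_flank_len = 80, extension = 5) {
  stopifnot(max_idr_len >= 1, min_flank_len >= 1, extension >= 1)
  structure(list(max_idr_len = as.integer(max_idr_len),
                 min_flank_len = as.integer(min_flank_len),
                 extension = as.integer(extension)),
            class = "short_idr_config")
}

#' Find short IDRs in a per-residue disorder flag vector
#'
#' @param idr_flags Logical vector of per-residue IDR calls (nonempty).
#' @param config A [short_idr_config()].
#' @return A list of class `region_annotation`: `n`, `idr` (the input
#'   flags), `short_idr` and `extended_short_idr`, each a tibble of
#'   1-based inclusive `start`/`end` intervals (disjoint, sorted).
#' @export
#' @examples
#' flags <- c(rep(FALSE, 100), rep(TRUE, 15), rep(FALSE, 100))
#' find_short_idrs(flags)$short_idr
find_short_idrs <- function(idr_flags, config = short_idr_config()) {
  stopifnot(length(idr_flags) > 0, is.logical(idr_flags))
  n <- length(idr_flags)
  r <- rle(idr_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)
  keep <- which(r$values &
                  r$lengths <= config$max_idr_len &
                  seq_len(k) > 1 & seq_len(k) < k)
  keep <- keep[r$lengths[keep - 1] >= config$min_flank_len &
                 r$lengths[keep + 1] >= config$min_flank_len]
  short <- tibble::tibble(start = starts[keep], end = ends[keep])
  ext <- tibble::tibble(start = pmax(1L, short$start - config$extension),
                        end = pmin(n, short$end + config$extension))
  structure(list(n = n, idr = idr_flags, short_idr = short,
                 extended_short_idr = ext),
            class = "region_annotation")
}

# Expand interval tibble to per-residue logical flags.
region_flags <- function(regions, n) {
  f <- logical(n)
  for (i in seq_len(nrow(regions))) {
    f[regions$start[i]:regions$end[i]] <- TRUE
  }
  f
}

#' Convert 1-based inclusive regions to BED-like 0-based half-open rows
#'
#' @param regions Tibble with `start`/`end` (1-based inclusive).
#' @param protein_id Chromosome-column value.
#' @return Tibble `protein_id`, `start` (0-based), `end` (half-open).
#' @export
regions_to_bed <- function(regions, protein_id) {
  tibble::tibble(protein_id = protein_id,
                 start = regions$start - 1L,
                 end = regions$end)
}

#' Classify residues into high/low side-chain exposure
#'
#' Residues with a raw side-chain pPSE at or below `cutoff` neighbours are
#' labelled `"high"` exposure, the rest `"low"` (boundary inclusive).
#'
#' @param profile A `ppse_profile` computed with the side-chain
#'   configuration (12 Angstrom, 70 degrees).
#' @param cutoff Inclusive neighbour-count cutoff.
#' @return Character vector (`"high"`/`"low"`) aligned with the profile.
#' @export
classify_exposure <- function(profile, cutoff = 5) {
  ifelse(profile$ppse <= cutoff, "high", "low")
}

#' Full per-residue structural annotation for one protein
#'
#' Runs the side-chain exposure (12 Angstrom / 70 degrees), the IDR caller
#' (24 Angstrom full sphere, smoothed), the short-IDR extractor and the
#' exposure classifier, and returns everything as one residue-level table.
#' Residues are eligible for 3D proximity analysis when they are structured
#' or inside a short IDR (long disordered runs are excluded).
#'
#' @param structure An `af_structure` tibble.
#' @param pae PAE matrix.
#' @param exposure_radius,exposure_angle Side-chain exposure configuration.
#' @param exposure_cutoff Inclusive high-exposure cutoff.
#' @param idr An [idr_config()].
#' @param short An [short_idr_config()].
#' @param use_pae Use the PAE for both exposure configurations.
#' @return A tibble with one row per residue: `protein_id`, `position`,
#'   `aa`, `plddt`, `ppse`, `ppse_full`, `ppse_smooth`, `idr`, `short_idr`,
#'   `extended_short_idr`, `exposure`, `eligible_proximity`.
#' @export
annotate_structure <- function(structure, pae,
                               exposure_radius = 12, exposure_angle = 70,
                               exposure_cutoff = 5,
                               idr = idr_config(), short = short_idr_config(),
                               use_pae = TRUE) {
  side <- compute_ppse(structure, pae, radius = exposure_radius,
                       angle = exposure_angle, use_pae = use_pae)
  idr_cfg <- idr
  idr_cfg$use_pae <- use_pae
  idr_tab <- call_idr(structure, pae, idr_cfg)
  regions <- find_short_idrs(idr_tab$idr, short)
  n <- nrow(structure)
  short_flag <- region_flags(regions$short_idr, n)
  ext_flag <- region_flags(regions$extended_short_idr, n)
  tibble::tibble(
    protein_id = structure$protein_id,
    position = structure$position,
    aa = structure$aa,
    plddt = structure$plddt,
    ppse = side$ppse,
    ppse_full = idr_tab$ppse_full,
    ppse_smooth = idr_tab$ppse_smooth,
    idr = idr_tab$idr,
    short_idr = short_flag,
    extended_short_idr = ext_flag,
    exposure = classify_exposure(side, exposure_cutoff),
    eligible_proximity = !idr_tab$idr | short_flag)
}

#' Annotate a whole set of proteins
#'
#' @param structures Named list of `af_structure` tibbles.
#' @param paes Named list of PAE matrices (names matching `structures`).
#' @param ... Passed to [annotate_structure()].
#' @return Row-bound residue annotation tibble across proteins.
#' @export
annotate_proteome <- function(structures, paes, ...) {
  stopifnot(length(structures) == length(paes))
  ids <- names(structures)
  dplyr::bind_rows(lapply(ids, function(id) {
    annotate_structure(structures[[id]], paes[[id]], ...)
  }))
}
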