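#' Describe one segment of a synthetic protein
#'
#' Segments are the building blocks of [make_chimera()]: ideal alpha-helices,
#' extended coils (emulating disordered stretches), and compact globules
#' (emulating folded domains). Each segment carries its own pLDDT level and
#' the PAE to use within the segment (`intra_pae`) and between this segment
#' and every other segment (`inter_pae`).
#'
#' @param kind `"helix"`, `"coil"` or `"globule"`.
#' @param length Residue count (>= 1).
#' @param plddt_level Mean per-residue pLDDT; defaults to 92 for structured
#'   kinds and 35 for coils, matching typical AlphaFold confidence in
#'   folded vs disordered regions.
#' @param intra_pae PAE (Angstrom) within the segment; defaults to 2 for
#'   structured kinds, 15 for coils.
#' @param inter_pae PAE between this segment and others; default 25,
#'   emulating the high relative-position uncertainty of domains linked by
#'   flexible regions.
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(kind = c("helix", "coil", "globule"), length,
                         plddt_level = NULL, intra_pae = NULL, inter_pae = 25) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 1) stop("segment length must be >= 1", call. = FALSE)
  plddt_level <- plddt_level %||% if (kind == "coil") 35 else 92
  intra_pae <- intra_pae %||% if (kind == "coil") 15 else 2
  if (intra_pae > inter_pae) {
    stop("intra_pae must not exceed inter_pae", call. = FALSE)
  }
  structure(list(kind = kind, length = length, plddt_level = plddt_level,
                 intra_pae = intra_pae, inter_pae = inter_pae),
            class = "segment_spec")
}

# Ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A/residue, 100 deg
# twist; consecutive CA-CA ~= 3.8 A. Axis along +x.
helix_ca <- function(len) {
  i <- seq_len(len) - 1
  theta <- i * 100 * pi / 180
  cbind(1.5 * i, 2.3 * cos(theta), 2.3 * sin(theta))
}

# Extended quasi-linear coil: unit steps of exactly 3.8 A along a jittered
# forward direction.
coil_ca <- function(len) {
  ca <- matrix(0, len, 3)
  if (len == 1) return(ca)
  for (i in 2:len) {
    dir <- c(1, stats::rnorm(2, 0, 0.25))
    ca[i, ] <- ca[i - 1, ] + 3.8 * dir / vnorm(dir)
  }
  ca
}

# Compact globule: serpentine space-filling walk on a 3.8 A grid inside a
# cube sized to the residue count, plus small Gaussian jitter. Guarantees
# high neighbor counts without simulation.
globule_ca <- function(len) {
  m <- ceiling(len^(1 / 3))
  cells <- matrix(0, m^3, 3)
  idx <- 0
  for (iz in 0:(m - 1)) {
    ys <- if (iz %% 2 == 0) 0:(m - 1) else (m - 1):0
    for (iy in ys) {
      xs <- if ((iy + iz) %% 2 == 0) 0:(m - 1) else (m - 1):0
      for (ix in xs) {
        idx <- idx + 1
        cells[idx, ] <- c(ix, iy, iz)
      }
    }
  }
  3.8 * cells[seq_len(len), , drop = FALSE] +
    matrix(stats::rnorm(3 * len, 0, 0.15), len, 3)
}

# Backbone N/C placed from the local chain tangent plus a perpendicular
# offset so that N, CA, C are never collinear and the ideal-tetrahedral
# pseudo-CB direction is well defined.
backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  N <- matrix(0, n, 3)
  C <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    t <- ca[hi, ] - ca[lo, ]
    if (vnorm(t) == 0) t <- c(1, 0, 0)
    t <- t / vnorm(t)
    ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    p <- ref - sum(ref * t) * t
    p <- p / vnorm(p)
    N[i, ] <- ca[i, ] - 1.2 * t + 0.6 * p
    C[i, ] <- ca[i, ] + 1.2 * t + 0.6 * p
  }
  list(N = N, C = C)
}

#' Generate a synthetic protein structure with matching PAE
#'
#' Concatenates segments ([segment_spec()]) along the chain: ideal helices,
#' extended coils, and compact globules, emulating the common architecture of
#' folded domains linked by short flexible regions. The PAE matrix is
#' `intra_pae` within each segment and, between two segments, the larger of
#' their `inter_pae` values. CB atoms are placed by ideal tetrahedral
#' geometry from N/CA/C; glycines get no CB. All randomness comes from a
#' private stream seeded with `seed`.
#'
#' @param segments List of [segment_spec()] objects (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param protein_id Accession recorded in the output.
#' @param sequence Optional one-letter sequence of the full length; defaults
#'   to a uniform random sequence over the 20 standard amino acids.
#' @return A list with elements `structure` (an `af_structure` tibble with a
#'   `segment` attribute giving per-segment start/end/kind) and `pae`
#'   (matrix).
#' @export
#' @examples
#' chim <- make_chimera(list(
#'   segment_spec("globule", 100), segment_spec("coil", 15),
#'   segment_spec("globule", 100)), seed = 42)
#' nrow(chim$structure)
make_chimera <- function(segments, seed, protein_id = "SYN1", sequence = NULL) {
  if (length(segments) < 1) stop("need at least one segment", call. = FALSE)
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  with_private_seed(seed, {
    lens <- vapply(segments, function(s) s$length, integer(1))
    n <- sum(lens)
    ca <- matrix(0, 0, 3)
    for (s in segments) {
      seg_ca <- switch(s$kind,
        helix = helix_ca(s$length),
        coil = coil_ca(s$length),
        globule = globule_ca(s$length))
      if (nrow(ca) > 0) {
        # translate so the new segment starts one bond past the chain so far
        offset <- c(max(ca[, 1]) + 3.8, 0, 0) - seg_ca[1, ]
        seg_ca <- sweep(seg_ca, 2, offset, `+`)
      }
      ca <- rbind(ca, seg_ca)
    }
    bb <- backbone_from_ca(ca)
    if (is.null(sequence)) {
      aa <- sample(AA1, n, replace = TRUE)
    } else {
      aa <- strsplit(sequence, "")[[1]]
      if (length(aa) != n) stop("sequence length must equal total segment length",
                                call. = FALSE)
    }
    cb <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      if (aa[i] != "G") cb[i, ] <- pseudo_cb(bb$N[i, ], ca[i, ], bb$C[i, ])
    }
    seg_id <- rep(seq_along(segments), lens)
    plddt <- pmin(100, pmax(0, vapply(segments, function(s) s$plddt_level,
                                      numeric(1))[seg_id] + stats::rnorm(n, 0, 1.5)))
    pae <- matrix(0, n, n)
    inter <- vapply(segments, function(s) s$inter_pae, numeric(1))
    intra <- vapply(segments, function(s) s$intra_pae, numeric(1))
    for (a in seq_along(segments)) {
      for (b in seq_along(segments)) {
        val <- if (a == b) intra[a] else max(inter[a], inter[b])
        pae[seg_id == a, seg_id == b] <- val
      }
    }
    diag(pae) <- 0
    res <- tibble::tibble(
      protein_id = protein_id, position = seq_len(n), author_pos = seq_len(n),
      aa = aa, n_x = bb$N[, 1], n_y = bb$N[, 2], n_z = bb$N[, 3],
      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
      c_x = bb$C[, 1], c_y = bb$C[, 2], c_z = bb$C[, 3],
      cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3], plddt = plddt)
    res <- res[, c("protein_id", "position", "author_pos", "aa",
                   "n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                   "c_x", "c_y", "c_z", "cb_x", "cb_y", "cb_z", "plddt")]
    out <- validate_af_structure(res)
    attr(out, "segments") <- tibble::tibble(
      segment = seq_along(segments),
      kind = vapply(segments, function(s) s$kind, character(1)),
      start = cumsum(lens) - lens + 1L, end = cumsum(lens))
    list(structure = out, pae = pae)
  })
}

#' Simulate PTM sites on a synthetic structure
#'
#' Each acceptor residue is modified independently with probability
#' `p_modify_exposed` when its raw pPSE is at most `exposure_cutoff` and
#' `p_modify_buried` otherwise. If `cluster_center` is given, acceptors
#' within `cluster_radius` (plain CA distance) of it are modified with
#' `p_modify_exposed` regardless of exposure, planting a 3D modification
#' hotspot.
#'
#' @param structure An `af_structure` tibble.
#' @param ppse A [compute_ppse()] profile on the same structure.
#' @param ptm_type PTM label (selects the acceptor set via `acceptor_map`).
#' @param p_modify_exposed,p_modify_buried Modification probabilities in
#'   `[0,1]`.
#' @param exposure_cutoff Raw pPSE cutoff splitting exposed from buried.
#' @param cluster_center Optional 1-based acceptor position.
#' @param cluster_radius Angstrom radius of the planted cluster.
#' @param seed Integer seed (private stream; deterministic).
#' @param acceptor_map Named list of acceptor residues per PTM type.
#' @return A PTM tibble (`protein_id`, `position`, `aa`, `ptm_type`,
#'   `regulatory`).
#' @export
simulate_ptm_sites <- function(structure, ppse, ptm_type = "p",
                               p_modify_exposed = 0.3, p_modify_buried = 0.3,
                               exposure_cutoff = 5,
                               cluster_center = NULL, cluster_radius = 8,
                               seed = 1, acceptor_map = ptm_acceptor_map()) {
  stopifnot(p_modify_exposed >= 0, p_modify_exposed <= 1,
            p_modify_buried >= 0, p_modify_buried <= 1)
  acceptors <- acceptor_map[[ptm_type]]
  if (is.null(acceptors)) stop("unknown ptm_type: ", ptm_type, call. = FALSE)
  is_acc <- structure$aa %in% acceptors
  pos <- structure$position[is_acc]
  p <- ifelse(ppse$ppse[is_acc] <= exposure_cutoff, p_modify_exposed, p_modify_buried)
  if (!is.null(cluster_center)) {
    if (!cluster_center %in% pos) {
      stop("cluster_center (", cluster_center, ") is not an acceptor residue",
           call. = FALSE)
    }
    ca <- ca_matrix(structure)
    d <- sqrt(colSums((t(ca[pos, , drop = FALSE]) - ca[cluster_center, ])^2))
    p[d <= cluster_radius] <- p_modify_exposed
  }
  with_private_seed(seed, {
    hit <- stats::runif(length(pos)) < p
    tibble::tibble(protein_id = structure$protein_id[1],
                   position = pos[hit],
                   aa = structure$aa[is_acc][hit],
                   ptm_type = ptm_type,
                   regulatory = FALSE)
  })
}

#' Write a simulated proteome to disk in standard formats
#'
#' Writes each protein's structure as PDB and its PAE as AlphaFold-style
#' JSON into `dir`, plus an optional combined PTM TSV, so downstream modules
#' can be exercised through their public file interfaces.
#'
#' @param chimeras Named list of [make_chimera()] results.
#' @param dir Output directory (created if missing).
#' @param ptm Optional PTM tibble to write as `ptm.tsv`.
#' @return Invisibly, a tibble of written paths.
#' @export
write_fixture_set <- function(chimeras, dir, ptm = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap(chimeras, function(ch, id) {
    spath <- file.path(dir, paste0(id, ".pdb"))
    ppath <- file.path(dir, paste0(id, "_pae.json"))
    write_pdb(ch$structure, spath)
    write_pae_json(ch$pae, ppath)
    tibble::tibble(protein_id = id, structure = spath, pae = ppath)
  })
  if (!is.null(ptm)) {
    readr::write_tsv(ptm, file.path(dir, "ptm.tsv"))
  }
  invisible(dplyr::bind_rows(paths))
}
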