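#' Read an AlphaFold-style predicted structure
#'
#' Parses a single-chain PDB or mmCIF file into a per-residue tibble. The
#' B-factor column is interpreted as the per-residue pLDDT confidence (0-100),
#' as in AlphaFold DB models. Residues are re-indexed to a contiguous 1..n
#' range in author order; the original author numbering is kept in
#' `author_pos`.
#'
#' @param path Path to a `.pdb`, `.cif`/`.mmcif` file; `.gz` variants are
#'   decompressed transparently.
#' @param protein_id Accession to record. Defaults to the `AF-<acc>-F1`
#'   accession embedded in AlphaFold DB filenames, or the file basename.
#' @return A tibble of class `af_structure` with one row per residue:
#'   `protein_id`, `position` (1..n), `author_pos`, `aa` (one-letter code),
#'   `plddt`, and coordinate columns `n_x..n_z`, `ca_x..ca_z`, `c_x..c_z`,
#'   `cb_x..cb_z` (the CB columns are `NA` for glycine).
#' @export
#' @examples
#' chim <- make_chimera(list(segment_spec("helix", 20)), seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(chim$structure, f)
#' read_af_structure(f, protein_id = "SYN1")
read_af_structure <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  raw_path <- path
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = sub("\\.gz$", "", paste0(".", tools::file_ext(sub("\\.gz$", "", path)))))
    con <- gzfile(path, open = "rt")
    writeLines(readLines(con), tmp)
    close(con)
    path <- tmp
  }
  if (is.null(protein_id)) {
    base <- basename(raw_path)
    m <- regmatches(base, regexec("^AF-([A-Z0-9]+)-F([0-9]+)", base))[[1]]
    if (length(m) == 3) {
      if (as.integer(m[3]) > 1) {
        stop("fragmented AlphaFold entries (fragment index > 1) are not supported: ",
             base, call. = FALSE)
      }
      protein_id <- m[2]
    } else {
      protein_id <- sub("\\.(pdb|cif|mmcif)(\\.gz)?$", "", base)
    }
  }
  is_cif <- grepl("\\.(cif|mmcif)$", path)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE) else
    bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", raw_path, call. = FALSE)
  chains <- unique(atoms$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1) {
    stop("expected a single chain, found ", length(chains), ": ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  as_structure_record(atoms, protein_id)
}

# Build the per-residue record from a bio3d-style atom table.
as_structure_record <- function(atoms, protein_id) {
  author_pos <- unique(atoms$resno)  # author order = order of appearance
  n <- length(author_pos)
  grab <- function(res_atoms, name) {
    i <- which(res_atoms$elety == name)
    if (length(i) == 0) return(NULL)
    as.numeric(res_atoms[i[1], c("x", "y", "z")])
  }
  rows <- vector("list", n)
  aa_vec <- character(n)
  unknown <- character(0)
  for (k in seq_len(n)) {
    ra <- atoms[atoms$resno == author_pos[k], , drop = FALSE]
    resid3 <- ra$resid[1]
    aa <- suppressWarnings(bio3d::aa321(resid3))
    if (is.na(aa) || !aa %in% AA1) {
      unknown <- c(unknown, resid3)
      aa <- "X"
    }
    aa_vec[k] <- aa
    ca <- grab(ra, "CA")
    if (is.null(ca)) {
      stop("residue ", resid3, " ", author_pos[k], " has no CA atom", call. = FALSE)
    }
    nn <- grab(ra, "N")
    cc <- grab(ra, "C")
    if (is.null(nn) || is.null(cc)) {
      stop("residue ", resid3, " ", author_pos[k],
           " lacks a backbone N or C atom", call. = FALSE)
    }
    cb <- grab(ra, "CB")
    plddt <- as.numeric(ra$b[ra$elety == "CA"][1])
    rows[[k]] <- c(nn, ca, cc, cb %||% rep(NA_real_, 3), plddt)
  }
  if (length(unknown) > 0) {
    warning("unknown residue name(s) mapped to 'X': ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                   "c_x", "c_y", "c_z", "cb_x", "cb_y", "cb_z", "plddt")
  res <- tibble::tibble(
    protein_id = protein_id,
    position = seq_len(n),
    author_pos = author_pos,
    aa = aa_vec
  )
  res <- dplyr::bind_cols(res, tibble::as_tibble(m))
  validate_af_structure(res)
}

validate_af_structure <- function(x) {
  if (any(!is.finite(x$plddt)) || any(x$plddt < 0 | x$plddt > 100)) {
    bad <- x$position[!is.finite(x$plddt) | x$plddt < 0 | x$plddt > 100]
    stop("pLDDT out of [0,100] at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  has_cb <- !is.na(x$cb_x)
  if (any(has_cb)) {
    d <- sqrt((x$ca_x - x$cb_x)^2 + (x$ca_y - x$cb_y)^2 + (x$ca_z - x$cb_z)^2)
    if (any(d[has_cb] >= 4)) {
      stop("CB further than 4 Å from CA at position(s) ",
           paste(utils::head(x$position[has_cb][d[has_cb] >= 4], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!identical(x$position, seq_len(nrow(x)))) {
    stop("residue positions are not contiguous 1..n", call. = FALSE)
  }
  class(x) <- c("af_structure", class(x))
  x
}

#' One-letter sequence of a structure
#' @param structure An `af_structure` tibble.
#' @return A single string of one-letter codes.
#' @export
structure_sequence <- function(structure) {
  paste(structure$aa, collapse = "")
}

# CA coordinates as an n x 3 matrix.
ca_matrix <- function(structure) {
  as.matrix(structure[, c("ca_x", "ca_y", "ca_z")])
}

#' Write a structure as a single-chain PDB file
#'
#' Emits N, CA, C and (where present) CB atoms with the pLDDT in the
#' B-factor column, mirroring the AlphaFold DB layout, so fixtures can be
#' round-tripped through the public file interface.
#'
#' @param structure An `af_structure` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(structure, path) {
  aa123 <- function(a) if (a == "X") "UNK" else bio3d::aa123(a)
  lines <- character(0)
  serial <- 0L
  fmt <- function(serial, name, resn, resno, xyz, b) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resn, "A", resno, xyz[1], xyz[2], xyz[3], 1, b,
            substr(name, 1, 1))
  }
  for (k in seq_len(nrow(structure))) {
    r <- structure[k, ]
    resn <- aa123(r$aa)
    for (atom in c("N", "CA", "C", "CB")) {
      pre <- tolower(atom)
      xyz <- c(r[[paste0(pre, "_x")]], r[[paste0(pre, "_y")]], r[[paste0(pre, "_z")]])
      if (any(is.na(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, atom, resn, r$position, xyz, r$plddt))
    }
  }
  lines <- c(lines, "TER", "END")
  write_lines_atomic(lines, path)
}

#' Read an AlphaFold predicted aligned error (PAE) matrix
#'
#' Supports both AlphaFold DB JSON dialects: the dense
#' `predicted_aligned_error` matrix and the older
#' `residue1`/`residue2`/`distance` triplet list. Diagonal entries are
#' clamped to zero at load.
#'
#' @param path Path to the JSON file (`.gz` supported).
#' @param n Optional expected dimension; a mismatch is an error.
#' @return An n x n numeric matrix (Angstrom).
#' @export
read_pae <- function(path, n = NULL) {
  if (!file.exists(path)) stop("PAE file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  close(con)
  j <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  if (is.list(j) && is.null(names(j)) && length(j) == 1) j <- j[[1]]
  if (!is.null(j$predicted_aligned_error)) {
    m <- j$predicted_aligned_error
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.numeric(m), nrow = nrow(m))
  } else if (!is.null(j$residue1)) {
    r1 <- as.integer(j$residue1)
    r2 <- as.integer(j$residue2)
    d <- as.numeric(j$distance)
    nn <- max(r1, r2)
    m <- matrix(NA_real_, nn, nn)
    m[cbind(r1, r2)] <- d
    if (anyNA(m)) stop("triplet PAE list does not cover the full matrix", call. = FALSE)
  } else {
    stop("unrecognized PAE JSON layout in ", path, call. = FALSE)
  }
  validate_pae(m, n = n)
}

validate_pae <- function(m, n = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("PAE matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("PAE entries must be finite and non-negative", call. = FALSE)
  }
  diag(m) <- 0
  if (!is.null(n) && nrow(m) != n) {
    stop("PAE dimension (", nrow(m), ") does not match structure length (", n, ")",
         call. = FALSE)
  }
  unname(m)
}

#' Write a PAE matrix as AlphaFold DB JSON
#'
#' @param pae An n x n matrix.
#' @param path Output path.
#' @param dialect `"dense"` (current AlphaFold DB layout) or `"triplet"`
#'   (older residue1/residue2/distance layout).
#' @return The path, invisibly.
#' @export
write_pae_json <- function(pae, path, dialect = c("dense", "triplet")) {
  dialect <- match.arg(dialect)
  pae <- validate_pae(pae)
  obj <- if (dialect == "dense") {
    list(list(predicted_aligned_error = pae,
              max_predicted_aligned_error = max(pae)))
  } else {
    idx <- expand.grid(residue2 = seq_len(nrow(pae)), residue1 = seq_len(nrow(pae)))
    list(list(residue1 = idx$residue1,
              residue2 = idx$residue2,
              distance = pae[cbind(idx$residue1, idx$residue2)],
              max_predicted_aligned_error = max(pae)))
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  write_lines_atomic(txt, path)
}

#' Fetch an AlphaFold DB model and PAE by accession
#'
#' Convenience downloader for `AF-<accession>-F1` model (PDB) and PAE JSON.
#' Requires network access; nothing in the package depends on it.
#'
#' @param accession UniProt accession.
#' @param dir Output directory.
#' @param version AlphaFold DB model version tag.
#' @return Named list with the two downloaded paths.
#' @export
fetch_afdb <- function(accession, dir = ".", version = "v4") {
  base <- sprintf("https://alphafold.ebi.ac.uk/files/AF-%s-F1", accession)
  pdb <- file.path(dir, sprintf("AF-%s-F1-model_%s.pdb", accession, version))
  pae <- file.path(dir, sprintf("AF-%s-F1-predicted_aligned_error_%s.json", accession, version))
  utils::download.file(sprintf("%s-model_%s.pdb", base, version), pdb, quiet = TRUE)
  utils::download.file(sprintf("%s-predicted_aligned_error_%s.json", base, version), pae, quiet = TRUE)
  list(structure = pdb, pae = pae)
}
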