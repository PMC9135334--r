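#' Canonical PTM acceptor residues
#'
#' Phosphorylation (`p`) on S/T/Y; ubiquitination (`ub`), sumoylation
#' (`sm`) and acetylation (`ac`) on K; methylation (`m`) on K/R; O-GalNAc
#' (`ga`) and O-GlcNAc (`gl`) on S/T.
#'
#' @return Named list mapping PTM type to one-letter acceptor codes.
#' @export
ptm_acceptor_map <- function() {
  list(p = c("S", "T", "Y"),
       ub = "K", sm = "K", ac = "K",
       m = c("K", "R"),
       ga = c("S", "T"), gl = c("S", "T"))
}

#' Read and filter a PTM site table
#'
#' Reads a TSV/CSV with columns `protein_id`, `position` (1-based), `aa`,
#' `ptm_type` and optionally `regulatory`. Filtering follows the standard
#' import rules: methylation subtypes are collapsed to one `m` type, sites
#' whose residue is not an acceptor of their PTM type are dropped (and
#' counted), duplicates on (protein, position, type) are collapsed, and
#' sites from the `regulatory` table that are missing from the main table
#' are added with `regulatory = TRUE`.
#'
#' @param path Path to the main PTM table (TSV or CSV by extension), or a
#'   data frame.
#' @param regulatory Optional path or data frame of regulatory sites (same
#'   columns, `regulatory` column not required).
#' @param acceptor_map Acceptor residues per type; see [ptm_acceptor_map()].
#' @param methyl_aliases Type labels collapsed into `m`.
#' @return A tibble of class `ptm_table` with a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
read_ptm_table <- function(path, regulatory = NULL,
                           acceptor_map = ptm_acceptor_map(),
                           methyl_aliases = c("m1", "m2", "m3", "me")) {
  tab <- read_site_file(path)
  if (!"regulatory" %in% names(tab)) tab$regulatory <- FALSE
  tab$regulatory <- as.logical(tab$regulatory)
  report <- list()
  if (!is.null(regulatory)) {
    reg <- read_site_file(regulatory)
    reg$regulatory <- TRUE
    reg <- reg[, c("protein_id", "position", "aa", "ptm_type", "regulatory")]
    in_main <- paste(reg$protein_id, reg$position, reg$ptm_type) %in%
      paste(tab$protein_id, tab$position, tab$ptm_type)
    tab$regulatory <- tab$regulatory |
      paste(tab$protein_id, tab$position, tab$ptm_type) %in%
        paste(reg$protein_id, reg$position, reg$ptm_type)
    report$regulatory_added <- sum(!in_main)
    tab <- dplyr::bind_rows(tab[, names(reg)], reg[!in_main, ])
  }
  bad_pos <- !is.finite(tab$position) | tab$position <= 0 |
    tab$position != round(tab$position)
  if (any(bad_pos)) {
    stop("malformed positions in rows: ",
         paste(utils::head(which(bad_pos), 10), collapse = ", "), call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  tab$ptm_type[tab$ptm_type %in% methyl_aliases] <- "m"
  known <- tab$ptm_type %in% names(acceptor_map)
  report$dropped_unknown_type <- sum(!known)
  tab <- tab[known, ]
  ok_acc <- mapply(function(aa, ty) aa %in% acceptor_map[[ty]],
                   tab$aa, tab$ptm_type)
  rejected <- table(tab$ptm_type[!ok_acc])
  for (ty in names(rejected)) {
    report[[paste0(ty, "_rejected")]] <- as.integer(rejected[[ty]])
  }
  tab <- tab[ok_acc, ]
  dup <- duplicated(tab[, c("protein_id", "position", "ptm_type")])
  report$duplicates_collapsed <- sum(dup)
  tab <- tab |>
    dplyr::group_by(.data$protein_id, .data$position, .data$ptm_type) |>
    dplyr::summarise(aa = .data$aa[1], regulatory = any(.data$regulatory),
                     .groups = "drop") |>
    dplyr::select("protein_id", "position", "aa", "ptm_type", "regulatory") |>
    dplyr::arrange(.data$protein_id, .data$position, .data$ptm_type)
  report$kept <- nrow(tab)
  attr(tab, "filter_report") <- report
  class(tab) <- c("ptm_table", class(tab))
  tab
}

read_site_file <- function(x) {
  if (is.data.frame(x)) {
    tab <- tibble::as_tibble(x)
  } else {
    reader <- if (grepl("\\.csv(\\.gz)?$", x)) readr::read_csv else readr::read_tsv
    tab <- reader(x, show_col_types = FALSE, progress = FALSE, comment = "#")
  }
  need <- c("protein_id", "position", "aa", "ptm_type")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("PTM table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Filtering report of a PTM table
#' @param x A `ptm_table` from [read_ptm_table()].
#' @return Named list of filter counts.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Join PTM sites to per-residue structural annotation
#'
#' Joins each site to the matching residue row of the annotation produced
#' by [annotate_structure()]/[annotate_proteome()]. Sites on proteins
#' without structure are dropped with a warning (or an error), and sites
#' whose residue letter disagrees with the structure sequence (including
#' out-of-bounds positions) are dropped and counted. A site is eligible for
#' 3D proximity analysis when its residue is structured or inside a short
#' IDR.
#'
#' @param ptm A `ptm_table` (or compatible tibble).
#' @param residues Residue annotation tibble.
#' @param on_unknown `"warn"` (drop unknown proteins) or `"error"`.
#' @return Annotated site tibble with the structural columns joined; the
#'   `mismatch_report` attribute reconciles dropped rows.
#' @export
annotate_ptm_sites <- function(ptm, residues, on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  known <- ptm$protein_id %in% residues$protein_id
  if (any(!known)) {
    msg <- paste0(sum(!known), " site(s) on proteins without structure")
    if (on_unknown == "error") stop(msg, call. = FALSE)
    warning(msg, ", dropped", call. = FALSE)
  }
  tab <- ptm[known, ]
  joined <- dplyr::left_join(
    tab,
    dplyr::rename(residues, struct_aa = "aa"),
    by = c("protein_id", "position"))
  ok <- !is.na(joined$struct_aa) & joined$struct_aa == joined$aa
  out <- joined[ok, ]
  out$struct_aa <- NULL
  attr(out, "mismatch_report") <- list(
    input = nrow(ptm),
    unknown_protein = sum(!known),
    sequence_mismatch = sum(!ok),
    kept = nrow(out))
  class(out) <- unique(c("annotated_ptm", class(out)))
  out
}

#' Extract a fixed-width sequence window around a site
#'
#' Returns the `2k + 1`-mer centered on `position`, padded with `_` where
#' the window overhangs a terminus. With `central` set, windows whose
#' central residue is not in the set are returned as `NA` (acceptor
#' validation).
#'
#' @param sequence One-letter protein sequence (single string).
#' @param position 1-based site position(s); vectorized.
#' @param k Flank width (default 6, i.e. 13-mers).
#' @param central Optional allowed central residues, e.g. `c("S","T","Y")`.
#' @return Character vector of windows.
#' @export
#' @examples
#' extract_window("MKSTR", 3)
extract_window <- function(sequence, position, k = 6, central = NULL) {
  n <- nchar(sequence)
  stopifnot(all(position >= 1), all(position <= n))
  padded <- paste0(strrep("_", k), sequence, strrep("_", k))
  w <- substr(rep(padded, length.out = length(position)),
              position, position + 2 * k)
  if (!is.null(central)) {
    mid <- substr(w, k + 1, k + 1)
    w[!mid %in% central] <- NA_character_
  }
  w
}

#' Read a motif pattern table
#'
#' Motifs are restricted regular expressions over amino-acid letters, `.`
#' and character classes, with exactly one capture group marking the
#' central acceptor position, e.g. `R.R..([ST])F`. Patterns are validated
#' at load.
#'
#' @param path TSV with columns `name`, `pattern`, or a data frame.
#' @return Tibble `name`, `pattern`.
#' @export
read_motifs <- function(path) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, comment = "#")
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("motif table needs columns name, pattern", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) validate_motif(tab$pattern[i], tab$name[i])
  tab
}

validate_motif <- function(pattern, name = pattern) {
  groups <- gregexpr("(?<!\\\\)\\((?!\\?)", pattern, perl = TRUE)[[1]]
  n_groups <- if (groups[1] == -1) 0 else length(groups)
  if (n_groups != 1) {
    stop("motif '", name, "' must have exactly one capture group marking ",
         "the central acceptor (found ", n_groups, ")", call. = FALSE)
  }
  ok <- tryCatch({
    suppressWarnings(grepl(pattern, "ACDEFG", perl = TRUE))
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("motif '", name, "' is not a valid pattern", call. = FALSE)
  invisible(TRUE)
}

#' Find all motif occurrences in protein sequences
#'
#' Every position where a pattern matches with its marked central acceptor
#' anchored at that position is reported; overlapping matches are all
#' reported (matching is done through a zero-width lookahead).
#'
#' @param sequences Named character vector of protein sequences.
#' @param motifs Motif tibble from [read_motifs()] (or compatible).
#' @return Tibble `protein_id`, `position` (of the marked center), `motif`.
#' @export
#' @examples
#' match_motifs(c(P1 = "ARTRQASFA"),
#'              data.frame(name = "rxrxxsf", pattern = "R.R..([ST])F"))
match_motifs <- function(sequences, motifs) {
  if (is.data.frame(motifs)) motifs <- read_motifs(motifs)
  stopifnot(!is.null(names(sequences)))
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    look <- paste0("(?=", motifs$pattern[i], ")")
    for (id in names(sequences)) {
      m <- gregexpr(look, sequences[[id]], perl = TRUE)[[1]]
      if (m[1] == -1) next
      cap <- attr(m, "capture.start")
      centers <- as.integer(cap[, 1])
      centers <- centers[centers > 0]
      if (length(centers) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          protein_id = id, position = centers, motif = motifs$name[i])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(protein_id = character(), position = integer(),
                          motif = character()))
  }
  dplyr::bind_rows(out)
}

#' Build a log-odds position-specific scoring matrix
#'
#' Scores are `log2` odds of the observed (pseudocount-regularized)
#' position-specific frequency against the background:
#' `score(a, pos) = log2(((count + pc * bg[a]) / (N_pos + pc)) / bg[a])`,
#' where `N_pos` counts non-padding letters in that column, so terminal `_`
#' padding contributes no evidence and an all-padding column scores zero.
#'
#' @param windows Character vector of aligned, equal-length windows (odd
#'   width).
#' @param background Named numeric vector of 20 amino-acid frequencies
#'   summing to 1 (default uniform).
#' @param pseudocount Total pseudocount mass, distributed proportionally to
#'   the background.
#' @return A `pssm`: 20 x (2k+1) numeric matrix (rows = amino acids,
#'   columns = offsets -k..k) with background and pseudocount attributes.
#' @export
build_pssm <- function(windows, background = NULL, pseudocount = 1) {
  stopifnot(length(windows) >= 1)
  width <- unique(nchar(windows))
  if (length(width) != 1) stop("windows must all have the same length", call. = FALSE)
  if (width %% 2 != 1) stop("window width must be odd", call. = FALSE)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA1)
  }
  background <- background[AA1]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    stop("background frequencies must cover the 20 amino acids and sum to 1",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(windows, ""))
  k <- (width - 1) / 2
  score <- matrix(0, 20, width, dimnames = list(AA1, as.character(-k:k)))
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[col != "_"]
    npos <- length(col)
    counts <- table(factor(col, levels = AA1))
    score[, j] <- log2(((as.numeric(counts) + pseudocount * background) /
                          (npos + pseudocount)) / background)
  }
  structure(score, k = k, pseudocount = pseudocount, background = background,
            n_windows = length(windows), class = c("pssm", "matrix", "array"))
}

#' Score a window against a PSSM
#' @param pssm A [build_pssm()] matrix.
#' @param window Window string of matching width; `_` padding scores 0.
#' @return Total log-odds score in bits.
#' @export
score_window <- function(pssm, window) {
  chars <- strsplit(window, "")[[1]]
  stopifnot(length(chars) == ncol(pssm))
  sum(vapply(seq_along(chars), function(j) {
    if (chars[j] == "_" || !chars[j] %in% rownames(pssm)) 0 else pssm[chars[j], j]
  }, numeric(1)))
}

#' Write a PSSM as a TSV matrix
#' @param pssm A [build_pssm()] matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  tab <- tibble::as_tibble(unclass(pssm), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(aa = rownames(pssm)), tab)
  write_tsv_atomic(tab, path)
}

#' Split annotated sites by side-chain exposure
#'
#' Partitions sites into high (`pPSE <= cutoff`) and low exposure sets and
#' draws a seeded uniform random subset of the high set matched in size to
#' the low set, for exposure-controlled motif comparisons. If the high set
#' is smaller than the low set the whole high set is returned with a
#' warning.
#'
#' @param annotated Annotated site tibble (needs a `ppse` column).
#' @param cutoff Inclusive high-exposure cutoff on the raw pPSE.
#' @param seed Integer seed for the matched subset.
#' @return List with tibbles `high`, `low`, `matched`.
#' @export
split_by_exposure <- function(annotated, cutoff = 5, seed = 1) {
  high <- annotated[annotated$ppse <= cutoff, ]
  low <- annotated[annotated$ppse > cutoff, ]
  if (nrow(high) < nrow(low)) {
    warning("high-exposure set smaller than low-exposure set; ",
            "matched subset is the entire high set", call. = FALSE)
    matched <- high
  } else {
    matched <- with_private_seed(seed, {
      high[sort(sample(nrow(high), nrow(low))), ]
    })
  }
  list(high = high, low = low, matched = matched)
}
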