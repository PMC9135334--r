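# internal helpers shared across modules

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(x, y) if (is.null(x)) y else x

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vunit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Run `expr` under a private RNG stream seeded with `seed`; the global
# .Random.seed is restored afterwards so package code never perturbs the
# caller's RNG state.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483587)
}

# Atomic text write: assemble lines, write to a sibling temp file, rename.
write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

# Serialize a tibble as TSV preceded by a provenance comment header.
write_tsv_atomic <- function(x, path, header = NULL) {
  body <- readr::format_tsv(x)
  body <- sub("\n$", "", body)
  lines <- c(header, strsplit(body, "\n", fixed = TRUE)[[1]])
  write_lines_atomic(lines, path)
}

tool_header <- function(config = list()) {
  sprintf("# structptm %s config=%s",
          as.character(utils::packageVersion("structptm")),
          rlang::hash(config))
}
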