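# Independent oracles and fixture builders shared across the suite.

# O(n^2) brute-force part-sphere exposure, written against the geometric
# definition (explicit acos in degrees), independent of the package's
# cosine-threshold implementation.
brute_force_ppse <- function(structure, pae, radius, angle, use_pae) {
  n <- nrow(structure)
  ca <- as.matrix(structure[, c("ca_x", "ca_y", "ca_z")])
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    cb <- c(structure$cb_x[i], structure$cb_y[i], structure$cb_z[i])
    if (any(is.na(cb))) {
      b <- ca[i, ] - c(structure$n_x[i], structure$n_y[i], structure$n_z[i])
      c2 <- c(structure$c_x[i], structure$c_y[i], structure$c_z[i]) - ca[i, ]
      a <- c(b[2] * c2[3] - b[3] * c2[2],
             b[3] * c2[1] - b[1] * c2[3],
             b[1] * c2[2] - b[2] * c2[1])
      cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c2 + ca[i, ]
    }
    v <- cb - ca[i, ]
    u[i, ] <- v / sqrt(sum(v^2))
  }
  raw <- integer(n)
  for (i in seq_len(n)) {
    diff <- sweep(ca, 2, ca[i, ], `-`)
    d <- sqrt(rowSums(diff^2))
    eff <- d
    if (use_pae) eff <- eff + pmax(pae[i, ], pae[, i])
    cosv <- pmin(1, pmax(-1, (diff %*% u[i, ]) / d))
    deg <- acos(cosv) * 180 / pi
    ok <- eff <= radius & deg <= angle
    ok[i] <- FALSE
    raw[i] <- sum(ok, na.rm = TRUE)
  }
  raw
}

# Exhaustive two-sided Fisher p-value from first principles: hypergeometric
# pmf via log-binomial coefficients, summing tables no more probable than
# the observed one.
enum_fisher_p <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  support <- max(0, col1 - row2):min(col1, row1)
  logp <- lchoose(row1, support) + lchoose(row2, col1 - support) -
    lchoose(n, col1)
  p <- exp(logp)
  min(1, sum(p[p <= p[support == a] * (1 + 1e-7)]))
}

# Closed-form BH on a plain vector (textbook step-up), for cross-checks.
closed_form_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Build a minimal valid structure record directly from CA coordinates
# (synthetic backbone; CB set explicitly or left NA for the pseudo-CB
# path).
toy_structure <- function(ca, aa = NULL, cb = NULL, plddt = 90,
                          protein_id = "TOY") {
  n <- nrow(ca)
  bb <- structptm:::backbone_from_ca(ca)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3)
  out <- tibble::tibble(
    protein_id = protein_id, position = seq_len(n), author_pos = seq_len(n),
    aa = aa,
    n_x = bb$N[, 1], n_y = bb$N[, 2], n_z = bb$N[, 3],
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    c_x = bb$C[, 1], c_y = bb$C[, 2], c_z = bb$C[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
    plddt = rep(plddt, length.out = n))
  class(out) <- c("af_structure", class(out))
  out
}

# A random mixed-architecture fixture with a rough random PAE overlay.
random_fixture <- function(seed, max_len = 200) {
  n1 <- 20 + seed %% 60
  n2 <- 5 + seed %% 12
  n3 <- max(10, max_len - n1 - n2 - 60)
  ch <- make_chimera(list(segment_spec("globule", n1),
                          segment_spec("coil", n2),
                          segment_spec("helix", n3)),
                     seed = seed, protein_id = paste0("FX", seed))
  n <- nrow(ch$structure)
  noise <- with_seed_local(seed + 1, matrix(stats::runif(n * n, 0, 4), n, n))
  pae <- ch$pae + noise
  diag(pae) <- 0
  list(structure = ch$structure, pae = pae)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Annotated three-segment proteome used by enrichment/proximity tests:
# one structure + annotation, reusable across modification replicates.
chimera_proteome <- function(n_proteins = 2, seed = 100, coil_len = 50,
                             globule_len = 100) {
  structures <- list()
  paes <- list()
  for (i in seq_len(n_proteins)) {
    id <- paste0("PROT", i)
    ch <- make_chimera(list(segment_spec("globule", globule_len),
                            segment_spec("coil", coil_len),
                            segment_spec("globule", globule_len)),
                       seed = seed + i, protein_id = id)
    structures[[id]] <- ch$structure
    paes[[id]] <- ch$pae
  }
  residues <- annotate_proteome(structures, paes)
  list(structures = structures, paes = paes, residues = residues)
}

# Uniform modification placement over the acceptors of a residue table.
uniform_sites <- function(residues, ptm_type = "p", p = 0.3, seed = 1,
                          acceptor_map = ptm_acceptor_map()) {
  acc <- residues[residues$aa %in% acceptor_map[[ptm_type]], ]
  hit <- with_seed_local(seed, stats::runif(nrow(acc)) < p)
  out <- acc[hit, c("protein_id", "position", "aa")]
  out$ptm_type <- ptm_type
  out$regulatory <- FALSE
  out
}
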