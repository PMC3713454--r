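# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form and never call the code paths they check.

# Needleman-Wunsch / Gotoh affine-gap global alignment score, O(nm) with
# explicit three-state recursion. Gap of length k costs open + k * ext
# (matching the Biostrings convention). Returns the optimal score only.
oracle_global_score <- function(a, b, submat, open = 10, ext = 0.5,
                                end_gap_free = FALSE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # align A[i] with B[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in B (A[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in A
  M[1, 1] <- 0
  init <- function(k) if (end_gap_free) 0 else -(open + k * ext)
  for (i in seq_len(n)) X[i + 1, 1] <- init(i)
  for (j in seq_len(m)) Y[1, j + 1] <- init(j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  if (!end_gap_free) return(max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  # free end gaps: best cell in the last row or column, ignoring trailing cost
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  for (i in 1:(n + 1)) best <- max(best, M[i, m + 1])
  for (j in 1:(m + 1)) best <- max(best, M[n + 1, j])
  best
}

# all-pairs clash enumeration
oracle_clashes <- function(xa, xb, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      if (d < cutoff) out <- rbind(out, c(i, j, d))
    }
  }
  out
}

# analytic SASA of two intersecting spheres of expanded radii r1, r2 at
# centre distance d: each sphere loses a cap of height h_i
oracle_two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) {
    big <- max(r1, r2)
    return(4 * pi * big^2)   # smaller sphere fully engulfed
  }
  h1 <- (r2^2 - (d - r1)^2) / (2 * d)
  h2 <- (r1^2 - (d - r2)^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# brute-force centered boxcar mean
oracle_window_average <- function(values, times, window) {
  sapply(seq_along(values), function(i) {
    sel <- abs(times - times[i]) <= window / 2 + 1e-12
    mean(values[sel])
  })
}

# random proper rotation via QR
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a tiny 3-atom single-residue PDB fixture
write_three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  invisible(path)
}

# minimal mmCIF fixture with the same three atoms
write_three_atom_cif <- function(path) {
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N ALA A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 C CA ALA A 1 1.458 0.000 0.000 1.00 1",
    "ATOM 3 C C ALA A 1 2.009 1.420 0.000 1.00 1",
    "#"), path)
  invisible(path)
}

# full His side chain (idealised-ish coordinates, correct connectivity) on a
# Gly-like backbone, for chi-angle tests
his_residue_structure <- function() {
  atoms <- data.frame(
    chain = "A", resno = 1L, insert = "", resid = "HIS",
    elety = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    element = c("N", "C", "C", "O", "C", "C", "N", "C", "C", "N"),
    x = c(-1.20, 0.00, 0.55, 0.00, 0.51, 0.60, 1.74, -0.37, 1.50, 0.28),
    y = c(0.80, 0.00, -1.30, -2.35, 1.00, 2.40, 3.15, 3.20, 4.42, 4.47),
    z = c(0.00, 0.00, -0.60, -0.55, 1.30, 2.20, 2.90, 2.45, 3.70, 3.45),
    stringsAsFactors = FALSE)
  new_structure(atoms, id = "synthetic-his")
}

# toy dimer with radii assigned to both subunits, for interface tests
toy_subunits <- function(params = toy_dimer_params()) {
  d <- make_toy_dimer(params)
  list(model = d,
       a = assign_radii(dimer_subunit(d, "A")),
       b = assign_radii(dimer_subunit(d, "B")),
       map = toy_domain_map(params$n_res))
}

# path to an optional real reference file (crystal structure or sequence set);
# see inst/extdata/reference/README.md
reference_path <- function(name) {
  system.file("extdata", "reference", name, package = "ectodimer")
}
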