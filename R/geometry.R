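#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (det = +1)
#' @param translation length-3 translation vector (Angstrom)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param tf a RigidTransform
#' @param xyz n x 3 coordinate matrix
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(tf, xyz) {
  stopifnot(inherits(tf, "RigidTransform"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(tf$rotation), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf a RigidTransform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -t(tf$rotation) %*% tf$translation)
}

#' Compose transforms (apply `a` after `b`)
#' @param a,b RigidTransforms
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Export a transform as JSON (row-major rotation + translation)
#' @param tf a RigidTransform
#' @param path output path
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(list(rotation = as.vector(t(tf$rotation)),
                            translation = tf$translation),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD between paired
#' coordinate sets, via SVD of the covariance matrix with reflection
#' correction. At least 3 non-collinear points are required.
#'
#' @param mobile n x 3 coordinates to move
#' @param reference n x 3 target coordinates (same row pairing)
#' @return list with `transform` (RigidTransform mapping mobile onto
#'   reference) and `rmsd` (Angstrom, after fitting)
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- matrix(as.numeric(as.matrix(mobile)), ncol = 3)
  reference <- matrix(as.numeric(as.matrix(reference)), ncol = 3)
  if (nrow(mobile) != nrow(reference)) stop("coordinate sets must pair row-for-row")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate input: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(A)$d[2] < 1e-8 * max(1, svd(A)$d[1]))
    stop("degenerate input: points are collinear")
  H <- crossprod(A, B)               # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  tf <- rigid_transform(R, t_vec)
  fitted <- apply_transform(tf, mobile)
  list(transform = tf, rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b n x 3 coordinate matrices, paired row-for-row
#' @param superpose if TRUE, report the RMSD after optimal rigid fitting;
#'   otherwise the raw deviation in the given frames
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- matrix(as.numeric(as.matrix(a)), ncol = 3)
  b <- matrix(as.numeric(as.matrix(b)), ncol = 3)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (superpose) kabsch_superpose(a, b)$rmsd
  else sqrt(mean(rowSums((a - b)^2)))
}

#' Anchors defining the domain-II bend angle
#'
#' Three residues marking the top, hinge, and bottom of the domain-II
#' dimerization face. For EGFR these are residues 194, 239, and 296; for other
#' receptors the equivalents are obtained through a residue equivalence map.
#'
#' @param top,hinge,bottom ResidueRef objects (see [residue_ref()])
#' @param atom atom name to measure between (default "CA")
#' @export
bend_anchors <- function(top, hinge, bottom, atom = "CA") {
  structure(list(top = top, hinge = hinge, bottom = bottom, atom = atom),
            class = "BendAnchors")
}

.anchor_xyz <- function(s, ref, atom) {
  a <- s$atoms
  hit <- a$chain == ref$chain & a$resno == ref$resno & a$insert == ref$insert &
    trimws(a$elety) == atom
  if (!any(hit)) stop("anchor atom ", atom, " not found for residue ", format(ref))
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Domain-II bend angle
#'
#' The interior angle (degrees) at the hinge anchor formed by the three anchor
#' atoms; 180 degrees is a straight domain II, smaller values are more bent.
#'
#' @param s a Structure
#' @param anchors a BendAnchors object
#' @return angle in degrees, in (0, 180]
#' @export
bend_angle <- function(s, anchors) {
  stopifnot(inherits(anchors, "BendAnchors"))
  p1 <- .anchor_xyz(s, anchors$top, anchors$atom)
  p2 <- .anchor_xyz(s, anchors$hinge, anchors$atom)
  p3 <- .anchor_xyz(s, anchors$bottom, anchors$atom)
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Cell-grid neighbor pairs between two coordinate sets within `cutoff`.
# Returns a 2-column index matrix. Used by clash detection and SASA.
.grid_pairs <- function(xa, xb, cutoff) {
  if (!nrow(xa) || !nrow(xb)) return(matrix(integer(), ncol = 2))
  cell <- max(cutoff, 1e-6)
  key <- function(m) {
    ix <- floor(m[, 1] / cell); iy <- floor(m[, 2] / cell); iz <- floor(m[, 3] / cell)
    list(ix = ix, iy = iy, iz = iz, k = paste(ix, iy, iz))
  }
  ka <- key(xa); kb <- key(xb)
  lookup <- split(seq_len(nrow(xb)), kb$k)
  out_i <- integer(); out_j <- integer()
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in seq_len(nrow(xa))) {
    neigh <- integer()
    for (o in seq_len(27)) {
      k <- paste(ka$ix[i] + off$dx[o], ka$iy[i] + off$dy[o], ka$iz[i] + off$dz[o])
      hit <- lookup[[k]]
      if (!is.null(hit)) neigh <- c(neigh, hit)
    }
    if (!length(neigh)) next
    d2 <- (xb[neigh, 1] - xa[i, 1])^2 + (xb[neigh, 2] - xa[i, 2])^2 +
      (xb[neigh, 3] - xa[i, 3])^2
    close <- neigh[d2 < cutoff^2]
    out_i <- c(out_i, rep.int(i, length(close)))
    out_j <- c(out_j, close)
  }
  cbind(out_i, out_j)
}

#' Detect steric clashes between two selections
#'
#' Reports all heavy-atom pairs closer than `cutoff`, sorted by distance.
#' Hydrogens are ignored (crystal structures generally lack them, and the
#' clash criterion is heavy-atom based).
#'
#' @param a,b Structures (disjoint atom sets)
#' @param cutoff distance threshold in Angstrom (default 2.5)
#' @return data.frame with one row per clashing pair: indices into each
#'   selection, residue identities, and the distance
#' @export
detect_clashes <- function(a, b, cutoff = 2.5) {
  stopifnot(inherits(a, "Structure"), inherits(b, "Structure"))
  a <- select_atoms(a, heavy_only = TRUE) |> suppressWarnings()
  b <- select_atoms(b, heavy_only = TRUE) |> suppressWarnings()
  xa <- coords(a); xb <- coords(b)
  pr <- .grid_pairs(xa, xb, cutoff)
  if (!nrow(pr)) {
    return(data.frame(i = integer(), j = integer(), chain_a = character(),
                      resno_a = integer(), elety_a = character(),
                      chain_b = character(), resno_b = integer(),
                      elety_b = character(), distance = numeric()))
  }
  d <- sqrt(rowSums((xa[pr[, 1], , drop = FALSE] - xb[pr[, 2], , drop = FALSE])^2))
  out <- data.frame(i = pr[, 1], j = pr[, 2],
                    chain_a = a$atoms$chain[pr[, 1]], resno_a = a$atoms$resno[pr[, 1]],
                    elety_a = trimws(a$atoms$elety[pr[, 1]]),
                    chain_b = b$atoms$chain[pr[, 2]], resno_b = b$atoms$resno[pr[, 2]],
                    elety_b = trimws(b$atoms$elety[pr[, 2]]),
                    distance = d)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Side-chain connectivity (heavy atoms) for the standard amino acids, used to
# find the atoms distal to a chi bond. CB connects back to CA (backbone).
.sidechain_bonds <- list(
  ARG = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","NE"), c("NE","CZ"),
             c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CA","CB"), c("CB","SG")),
  GLN = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","NE2")),
  GLU = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","OE2")),
  HIS = list(c("CA","CB"), c("CB","CG"), c("CG","ND1"), c("CG","CD2"),
             c("ND1","CE1"), c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","CE"), c("CE","NZ")),
  MET = list(c("CA","CB"), c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CA","CB"), c("CB","CG"), c("CG","CD")),
  SER = list(c("CA","CB"), c("CB","OG")),
  THR = list(c("CA","CB"), c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","NE1"), c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"),
             c("CE2","CZ2"), c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"),
             c("CZ","OH")),
  VAL = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"))
)

# Chi dihedral atom quadruples per residue type (standard conventions).
.chi_defs <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' Number of defined chi angles for a residue type
#' @param resid 3-letter residue name
#' @export
n_chi <- function(resid) length(.chi_defs[[toupper(resid)]])

#' Dihedral angle defined by four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors
#' @return dihedral in degrees in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
  m1 <- c(n1[2]*b2[3]-n1[3]*b2[2], n1[3]*b2[1]-n1[1]*b2[3], n1[1]*b2[2]-n1[2]*b2[1]) /
    sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Measure a side-chain chi angle
#' @param s a Structure
#' @param residue a ResidueRef
#' @param chi chi index (1-4)
#' @return dihedral in degrees
#' @export
get_chi_angle <- function(s, residue, chi) {
  at <- .chi_atoms(s, residue, chi)
  dihedral(at$p[1, ], at$p[2, ], at$p[3, ], at$p[4, ])
}

.chi_atoms <- function(s, residue, chi) {
  a <- s$atoms
  rows <- which(a$chain == residue$chain & a$resno == residue$resno &
                  a$insert == residue$insert)
  if (!length(rows)) stop("residue ", format(residue), " not found")
  resid <- toupper(a$resid[rows[1]])
  defs <- .chi_defs[[resid]]
  if (is.null(defs) || chi > length(defs))
    stop("chi", chi, " is not defined for residue type ", resid)
  quad <- defs[[chi]]
  idx <- vapply(quad, function(nm) {
    h <- rows[trimws(a$elety[rows]) == nm]
    if (!length(h)) stop("atom ", nm, " missing in residue ", format(residue))
    h[1]
  }, integer(1))
  list(rows = rows, resid = resid, quad = quad, idx = idx,
       p = as.matrix(a[idx, c("x", "y", "z")]))
}

#' Rotate a side-chain chi angle
#'
#' Rotates all side-chain atoms distal to the chi bond rigidly about the bond
#' axis by `delta` degrees. Bond lengths and angles are untouched; backbone
#' atoms never move.
#'
#' @param s a Structure
#' @param residue a ResidueRef
#' @param chi chi index (1-4); must be defined for the residue type
#' @param delta rotation in degrees (added to the current chi)
#' @return Structure with the rotated side chain
#' @export
set_chi_angle <- function(s, residue, chi, delta) {
  at <- .chi_atoms(s, residue, chi)
  a <- s$atoms
  # atoms that move: everything connected beyond the 3rd dihedral atom,
  # walking the side-chain bond graph away from the 2nd atom
  bonds <- .sidechain_bonds[[at$resid]]
  adj <- list()
  for (bd in bonds) {
    adj[[bd[1]]] <- c(adj[[bd[1]]], bd[2])
    adj[[bd[2]]] <- c(adj[[bd[2]]], bd[1])
  }
  from <- at$quad[3]; block <- at$quad[2]
  moving <- character(); frontier <- setdiff(adj[[from]], block)
  while (length(frontier)) {
    moving <- union(moving, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier])), c(moving, from, block))
  }
  nm <- trimws(a$elety[at$rows])
  mv_rows <- at$rows[nm %in% moving]
  # hydrogens ride with their parent heavy atom: HD1/1HD1 etc. follow CD1/ND1;
  # hydrogens bonded to the rotating-bond atom itself (e.g. HB* for chi1) move too
  suffixes <- unique(c(substring(moving, 2), substring(at$quad[3], 2)))
  suffixes <- suffixes[nzchar(suffixes)]
  hn <- sub("^[0-9]*H", "", nm)                       # "1HD1" / "HD1" -> "D1" / "D11"
  is_h <- a$element[at$rows] == "H" & grepl("^[0-9]*H", nm)
  h_match <- is_h & (hn %in% suffixes | sub("[0-9]$", "", hn) %in% suffixes)
  mv_rows <- union(mv_rows, at$rows[h_match])
  axis_from <- at$p[2, ]; axis_to <- at$p[3, ]
  u <- axis_to - axis_from; u <- u / sqrt(sum(u^2))
  th <- delta * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)   # Rodrigues
  xyz <- as.matrix(a[mv_rows, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, axis_from)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, -axis_from)
  a[mv_rows, c("x", "y", "z")] <- xyz
  s$atoms <- a
  s
}
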