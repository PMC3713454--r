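#' Trajectory: ordered coordinate frames over a fixed topology
#'
#' @param topology a Structure giving atom identities (its own coordinates are
#'   frame 1 unless `xyz` says otherwise)
#' @param xyz frames x (3*natoms) coordinate matrix (bio3d xyz layout:
#'   x1,y1,z1,x2,...)
#' @param times frame times in nanoseconds (strictly increasing)
#' @return an object of class `Trajectory`
#' @export
new_trajectory <- function(topology, xyz, times) {
  stopifnot(inherits(topology, "Structure"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms(topology))
    stop("xyz has ", ncol(xyz), " columns; topology needs ", 3 * n_atoms(topology))
  if (length(times) != nrow(xyz)) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a Trajectory
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as a Structure
#' @param traj a Trajectory
#' @param i frame index (1-based)
#' @export
frame_structure <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame ", i, " out of range")
  set_coords(traj$topology, matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE))
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ns\n",
              n_frames(x), n_atoms(x$topology), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a multi-model PDB as a trajectory
#'
#' Frame times default to 0, dt, 2*dt, ... ns.
#'
#' @param path multi-model PDB path
#' @param dt frame spacing in ns
#' @export
read_trajectory_pdb <- function(path, dt = 20) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path, format = "pdb", model = 1)
  # align xyz columns with the (water/altloc-filtered) topology atom order
  a <- pdb$atom
  keep <- !(a$resid %in% .water_resids)
  xyz_idx <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  xyz <- pdb$xyz[, xyz_idx, drop = FALSE]
  if (ncol(xyz) != 3 * n_atoms(topo))
    stop("could not reconcile multi-model atoms with topology (altloc records?)")
  new_trajectory(topo, xyz, times = (seq_len(nrow(xyz)) - 1) * dt)
}

#' Write a trajectory as a multi-model PDB
#' @param traj a Trajectory
#' @param path output path
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  a <- traj$topology$atoms
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", i), con)
    ai <- a
    m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
    ai$x <- m[, 1]; ai$y <- m[, 2]; ai$z <- m[, 3]
    .write_pdb_model(con, ai)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}
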