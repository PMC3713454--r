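# Synthetic structures with the geometric features the analysis assumes: an
# arm with a tunable hinge bend (standing in for domain II), a two-arm dimer
# with a tunable interface gap, and pseudo-trajectories interpolating between
# closed and open states. Residues are a CA trace plus one pseudo side-chain
# sphere ("CB", radius 1.9 A) so SASA and clash machinery have volume to act
# on; deliberately non-physical.

.toy_spacing <- 3.8   # CA-CA virtual bond, A
.toy_cb_radius <- 1.9

#' Parameters for a synthetic two-arm dimer
#'
#' @param bend domain-II-like bend angle per subunit, degrees, in (0, 180]
#' @param gap interface gap in Angstrom (>= 0): the N-terminal half of the
#'   second arm is translated away from the interface by this amount,
#'   emulating the V-shaped opening of a ligand-free dimer interface
#' @param n_res residues per subunit (>= 9)
#' @param noise_sd i.i.d. Gaussian coordinate noise, A (>= 0)
#' @param seed RNG seed
#' @export
toy_dimer_params <- function(bend = 180, gap = 0, n_res = 40, noise_sd = 0,
                             seed = 1L) {
  if (bend <= 0 || bend > 180) stop("bend must be in (0, 180]")
  if (gap < 0) stop("gap must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_res < 9) stop("n_res must be >= 9")
  list(bend = bend, gap = gap, n_res = as.integer(n_res),
       noise_sd = noise_sd, seed = as.integer(seed))
}

# CA positions of an arm: first half along +y, second half bending by
# (180 - bend) degrees at the hinge, in the xy-plane. A small alternating
# z-dither keeps C-alpha segments non-collinear (so rigid fits on sub-ranges
# are well conditioned, as for a real backbone); it is zeroed at the three
# bend-anchor residues so the anchor angle is exact by construction.
.toy_dither <- 0.3
.arm_ca <- function(bend, n_res) {
  hinge <- (n_res + 1L) %/% 2L
  th <- (180 - bend) * pi / 180
  dir1 <- c(0, 1, 0)
  dir2 <- c(sin(th), cos(th), 0)
  xyz <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    d <- if (i <= hinge) dir1 else dir2
    xyz[i, ] <- xyz[i - 1, ] + .toy_spacing * d
  }
  xyz[, 3] <- .toy_dither * rep_len(c(-1, 1), n_res)
  xyz[c(1L, hinge, n_res), 3] <- 0
  list(xyz = xyz, hinge = hinge)
}

#' Synthetic bent arm (domain-II stand-in)
#'
#' A CA-trace arm whose designated bend anchors (first, hinge, last residue)
#' reproduce the requested bend angle exactly at zero noise. Optionally each
#' residue also carries a pseudo side-chain sphere.
#'
#' @param bend bend angle in degrees, in (0, 180]
#' @param n_res number of residues (>= 9)
#' @param noise_sd Gaussian coordinate noise sd, A
#' @param seed RNG seed
#' @param chain chain id
#' @param sidechains add a "CB" pseudo-atom per residue
#' @return a Structure with attribute `anchors` (a [bend_anchors()] object)
#' @export
make_toy_arm <- function(bend, n_res = 21, noise_sd = 0, seed = 1L,
                         chain = "A", sidechains = FALSE) {
  if (bend <= 0 || bend > 180) stop("bend must be in (0, 180]")
  if (n_res < 9) stop("n_res must be >= 9 so the three anchors are distinct")
  arm <- .arm_ca(bend, n_res)
  atoms <- data.frame(chain = chain, resno = seq_len(n_res), insert = "",
                      resid = "GLY", elety = "CA", element = "C",
                      x = arm$xyz[, 1], y = arm$xyz[, 2], z = arm$xyz[, 3],
                      stringsAsFactors = FALSE)
  if (sidechains) {
    cb <- atoms
    cb$elety <- "CB"
    cb$x <- cb$x + 1.5   # side-chain spheres point along +x
    atoms <- rbind(atoms, cb)
    atoms <- atoms[order(atoms$resno, atoms$elety), ]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(atoms), sd = noise_sd), ncol = 3)
  }
  s <- new_structure(atoms, id = "synthetic-arm")
  attr(s, "anchors") <- bend_anchors(residue_ref(chain, 1),
                                     residue_ref(chain, arm$hinge),
                                     residue_ref(chain, n_res))
  s
}

#' Synthetic two-arm dimer with a tunable interface gap
#'
#' Two arms (chains A and B) run antiparallel with their pseudo side-chain
#' spheres facing each other across the interface. At `gap = 0` the spheres
#' interdigitate closely and the buried interface area is large; increasing
#' `gap` translates the N-terminal half of chain B away from the interface,
#' opening a V-shaped gap and monotonically reducing the buried area.
#'
#' @param params a [toy_dimer_params()] list
#' @return a `DimerModel` (see [new_dimer_model()]) with chains A and B;
#'   attribute `anchors` holds per-chain bend anchors
#' @export
make_toy_dimer <- function(params = toy_dimer_params()) {
  n <- params$n_res
  armA <- .arm_ca(params$bend, n)
  armB <- .arm_ca(params$bend, n)
  # interface normal is x; side chains of A point +x, of B point -x, and the
  # post-hinge halves bend away from the interface on both sides
  sepa <- 2 * 1.5 + 2 * .toy_cb_radius + 0.2   # CA-CA separation: CB spheres ~touch
  mk <- function(arm, chain, xoff, cbsign) {
    ca <- arm$xyz
    if (cbsign > 0) {            # proper 180-degree rotation about y, so each
      ca[, 1] <- -ca[, 1]        # arm is a rigid (not mirrored) copy of the
      ca[, 3] <- -ca[, 3]        # canonical arm and bends away from the interface
    }
    ca[, 1] <- ca[, 1] + xoff
    cb <- ca
    cb[, 1] <- cb[, 1] + cbsign * 1.5
    at <- rbind(
      data.frame(chain = chain, resno = seq_len(n), insert = "", resid = "GLY",
                 elety = "CA", element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                 stringsAsFactors = FALSE),
      data.frame(chain = chain, resno = seq_len(n), insert = "", resid = "GLY",
                 elety = "CB", element = "C", x = cb[, 1], y = cb[, 2], z = cb[, 3],
                 stringsAsFactors = FALSE))
    at[order(at$resno, at$elety), ]
  }
  atA <- mk(armA, "A", -sepa / 2, +1)
  atB <- mk(armB, "B", +sepa / 2, -1)
  # gap: swing chain B away from the interface (+x) in a V anchored at its
  # C-terminus; the N-terminal tip moves by the full gap, so moderate gaps
  # separate the N-terminal portion first and a large gap empties the
  # whole interface
  w <- 0.25 + 0.75 * (n - atB$resno) / (n - 1)   # pivot lies beyond the C-term
  atB$x <- atB$x + params$gap * w
  atoms <- rbind(atA, atB)
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(atoms), sd = params$noise_sd), ncol = 3)
  }
  s <- new_structure(atoms, id = "synthetic-dimer")
  hinge <- (n + 1L) %/% 2L
  attr(s, "anchors") <- list(
    A = bend_anchors(residue_ref("A", 1), residue_ref("A", hinge), residue_ref("A", n)),
    B = bend_anchors(residue_ref("B", 1), residue_ref("B", hinge), residue_ref("B", n)))
  new_dimer_model(s, receptor_chains = c("A", "B"),
                  provenance = list(list(step = "make_toy_dimer",
                                         params = params)))
}

#' Domain map for the synthetic arm/dimer
#'
#' Thirds of the arm are labelled I, II, III so domain-restricted metrics are
#' exercisable on toy structures.
#'
#' @param n_res residues per subunit
#' @export
toy_domain_map <- function(n_res = 40) {
  b1 <- max(1L, n_res %/% 3L); b2 <- max(b1 + 1L, (2L * n_res) %/% 3L)
  domain_map("synthetic", I = c(1, b1), II = c(b1 + 1, b2), III = c(b2 + 1, n_res))
}

#' Parameters for a synthetic pseudo-trajectory
#'
#' @param start,end [toy_dimer_params()] for the first and last frame (must
#'   share `n_res` and `bend` topology)
#' @param n_frames number of frames (>= 1)
#' @param spacing_ns frame spacing in ns (> 0). Default 20 ns, so that a
#'   200-ns averaging window spans 10 frames
#' @param noise_sd per-frame Gaussian coordinate noise, A
#' @param seed RNG seed
#' @export
pseudo_trajectory_params <- function(start, end, n_frames = 25, spacing_ns = 20,
                                     noise_sd = 0, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (spacing_ns <= 0) stop("spacing_ns must be > 0")
  if (start$n_res != end$n_res) stop("start and end must share n_res")
  list(start = start, end = end, n_frames = as.integer(n_frames),
       spacing_ns = spacing_ns, noise_sd = noise_sd, seed = as.integer(seed))
}

#' Synthetic pseudo-trajectory between two dimer states
#'
#' Frames interpolate linearly from the start-parameter geometry to the
#' end-parameter geometry (e.g. closed gap to open gap), with i.i.d. Gaussian
#' coordinate noise added per frame. Deterministic under a fixed seed. This
#' is a desk-scale stand-in for microsecond MD trajectories: it reproduces
#' the monotone interface-opening trend and the frame bookkeeping, not any
#' physical dynamics.
#'
#' @param params a [pseudo_trajectory_params()] list
#' @return a Trajectory over the start dimer's topology
#' @export
make_pseudo_trajectory <- function(params) {
  s0 <- make_toy_dimer(modifyList(params$start, list(noise_sd = 0)))
  s1 <- make_toy_dimer(modifyList(params$end, list(noise_sd = 0)))
  x0 <- as.vector(t(coords(s0$structure)))
  x1 <- as.vector(t(coords(s1$structure)))
  nf <- params$n_frames
  w <- if (nf == 1) 0 else (seq_len(nf) - 1) / (nf - 1)
  xyz <- outer(1 - w, x0) + outer(w, x1)
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = params$noise_sd),
                        nrow = nf)
  }
  new_trajectory(s0$structure, xyz, times = (seq_len(nf) - 1) * params$spacing_ns)
}
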