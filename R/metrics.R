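# Heavy-atom van der Waals radii (Angstrom). Chothia-style protein set; the
# shipped JSON config (extdata/atom_radii.json) carries the same values and
# can be overridden by the user.
.default_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                    SE = 1.90, H = 1.20, D = 1.20)
.fallback_radius <- 1.80

#' Load the atom-radius table
#' @param path JSON config mapping element symbol to radius (Angstrom);
#'   default is the shipped set
#' @return named numeric vector
#' @export
load_radii <- function(path = system.file("extdata", "atom_radii.json",
                                          package = "ectodimer")) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Assign van der Waals radii to the atoms of a Structure
#'
#' @param s a Structure
#' @param radii named vector element -> radius (Angstrom)
#' @param fallback radius for unlisted elements; NA to error instead
#' @return Structure with the `radius` column filled
#' @export
assign_radii <- function(s, radii = .default_radii, fallback = .fallback_radius) {
  r <- radii[s$atoms$element]
  if (anyNA(r)) {
    if (is.na(fallback)) {
      bad <- unique(s$atoms$element[is.na(r)])
      stop("no radius for element(s): ", paste(bad, collapse = ", "))
    }
    r[is.na(r)] <- fallback
  }
  s$atoms$radius <- as.numeric(r)
  s
}

# Deterministic near-uniform unit-sphere quadrature (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the heavy atoms: each atom's accessible area is
#' the fraction of quadrature points on its expanded sphere (radius + probe)
#' not buried inside any neighbour's expanded sphere, times the sphere area.
#' Hydrogens and waters are excluded.
#'
#' @param s a Structure with radii assigned (see [assign_radii()]); atoms
#'   without a radius raise an error naming the first offender
#' @param probe probe radius in Angstrom (default 1.4, a water molecule)
#' @param points quadrature points per atom (default 960)
#' @return a `SasaResult`: list with `area` (per heavy atom, Angstrom^2),
#'   `total`, `atoms` (the heavy-atom table), `probe`, `points`
#' @export
sasa <- function(s, probe = 1.4, points = 960) {
  stopifnot(inherits(s, "Structure"))
  h <- suppressWarnings(select_atoms(s, heavy_only = TRUE))
  if (!n_atoms(h)) stop("no heavy atoms to compute SASA on")
  if (anyNA(h$atoms$radius)) {
    i <- which(is.na(h$atoms$radius))[1]
    stop("atom without assigned radius: ", h$atoms$elety[i], " in residue ",
         h$atoms$chain[i], "/", h$atoms$resno[i], "; call assign_radii() first")
  }
  xyz <- coords(h)
  rad <- h$atoms$radius + probe
  n <- nrow(xyz)
  sp <- .sphere_points(points)
  # neighbour lists within the largest possible overlap distance
  pr <- .grid_pairs(xyz, xyz, 2 * max(rad))
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  nb <- split(pr[, 2], factor(pr[, 1], levels = seq_len(n)))
  area <- numeric(n)
  # decorrelate the lattice across atoms with a deterministic per-atom
  # rotation; otherwise regular structures alias against the shared point
  # set. The rotation is derived from the atom's own coordinates so it is
  # invariant to atom order and to sub-setting (an atom's quadrature is the
  # same whether its subunit is evaluated alone or in a complex).
  for (i in seq_len(n)) {
    a1 <- (xyz[i, 1] * 12.9898 + xyz[i, 2] * 78.233 + xyz[i, 3] * 37.719) %% (2 * pi)
    a2 <- (xyz[i, 1] * 93.989 + xyz[i, 2] * 67.345 + xyz[i, 3] * 10.123) %% (2 * pi)
    Rz <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)), 3, 3,
                 byrow = TRUE)
    pts <- sweep((sp %*% t(Rz %*% Ry)) * rad[i], 2, xyz[i, ], "+")
    js <- nb[[i]]
    acc <- rep(TRUE, points)
    for (j in js) {
      if (!any(acc)) break
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (d2 > rad[j]^2)
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / points
  }
  structure(list(area = area, total = sum(area), atoms = h$atoms,
                 probe = probe, points = points),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d heavy atoms (probe %.2f A, %d points)\n",
              x$total, length(x$area), x$probe, x$points))
  invisible(x)
}

.combine_structures <- function(a, b) {
  out <- a
  out$atoms <- rbind(a$atoms, b$atoms)
  rownames(out$atoms) <- NULL
  out
}

#' Buried interface area between two subunits, restricted to chosen domains
#'
#' Computes SASA(A) + SASA(B) - SASA(A united with B), summing per-atom
#' contributions only over atoms whose residue falls in the requested domains
#' of either subunit (domains I-III by default, matching how ErbB ectodomain
#' interfaces are reported: domain IV contacts are excluded). Ligand chains
#' are excluded unless their atoms are part of the supplied selections.
#'
#' @param a,b Structures for the two subunits (e.g. from [select_atoms()] or
#'   [dimer_subunit()]); both must be non-empty
#' @param restrict domain labels to count, or NULL for all atoms
#' @param domain_map_a,domain_map_b DomainMaps used for the restriction (the
#'   single `domain_map` argument sets both)
#' @param domain_map convenience: one map for both subunits
#' @param probe,points SASA parameters
#' @return buried area in Angstrom^2
#' @export
buried_interface_area <- function(a, b, restrict = c("I", "II", "III"),
                                  domain_map = NULL, domain_map_a = domain_map,
                                  domain_map_b = domain_map,
                                  probe = 1.4, points = 960) {
  stopifnot(inherits(a, "Structure"), inherits(b, "Structure"))
  if (!n_atoms(a) || !n_atoms(b)) stop("both subunit selections must be non-empty")
  sa <- sasa(a, probe, points)
  sb <- sasa(b, probe, points)
  sab <- sasa(.combine_structures(a, b), probe, points)
  na <- length(sa$area)
  d_a <- sa$area - sab$area[seq_len(na)]
  d_b <- sb$area - sab$area[na + seq_along(sb$area)]
  in_doms <- function(res, dm) {
    if (is.null(restrict)) return(rep(TRUE, length(res)))
    if (is.null(dm)) stop("domain restriction requires a domain_map")
    keep <- rep(FALSE, length(res))
    for (d in restrict) {
      iv <- dm$domains[[d]]
      if (is.null(iv)) stop("domain ", d, " absent from map for ", dm$receptor)
      keep <- keep | (res >= iv[1] & res <= iv[2])
    }
    keep
  }
  sum(d_a[in_doms(sa$atoms$resno, domain_map_a)]) +
    sum(d_b[in_doms(sb$atoms$resno, domain_map_b)])
}

#' Sliding-window (boxcar) average of a time series
#'
#' Centered mean over all samples within half a window of each time point;
#' edge windows are truncated, never padded.
#'
#' @param values numeric series
#' @param times sample times (ns), strictly increasing
#' @param window window width (ns); must be > 0
#' @return numeric vector of windowed values, same length as `values`
#' @export
window_average <- function(values, times, window) {
  if (window <= 0) stop("window must be > 0")
  if (length(values) != length(times)) stop("values and times differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  half <- window / 2
  vapply(seq_along(values), function(i) {
    mean(values[times >= times[i] - half & times <= times[i] + half])
  }, numeric(1))
}

#' Per-frame buried interface area over a trajectory
#'
#' @param traj a Trajectory whose topology contains both subunits
#' @param chains_a,chains_b chain ids of the two subunits
#' @param restrict,domain_map,probe,points passed to
#'   [buried_interface_area()]
#' @param window averaging window in ns (default 200, the conventional
#'   smoothing for microsecond-scale interface plots); set NULL to skip
#' @param radii radius table for [assign_radii()]
#' @return an `InterfaceSeries`: data.frame-like list with `times`, `values`,
#'   `window`, `windowed`
#' @export
interface_series <- function(traj, chains_a, chains_b,
                             restrict = c("I", "II", "III"), domain_map = NULL,
                             probe = 1.4, points = 960, window = 200,
                             radii = .default_radii) {
  stopifnot(inherits(traj, "Trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- assign_radii(frame_structure(traj, i), radii)
    a <- suppressWarnings(select_atoms(fr, chain = chains_a, het = FALSE))
    b <- suppressWarnings(select_atoms(fr, chain = chains_b, het = FALSE))
    if (!n_atoms(a) || !n_atoms(b))
      stop("frame ", i, ": subunit selection empty (topology mismatch?)")
    buried_interface_area(a, b, restrict = restrict, domain_map = domain_map,
                          probe = probe, points = points)
  }, numeric(1))
  wv <- if (is.null(window)) NULL else window_average(vals, traj$times, window)
  structure(list(times = traj$times, values = vals,
                 window = window, windowed = wv),
            class = "InterfaceSeries")
}

#' @export
print.InterfaceSeries <- function(x, ...) {
  cat(sprintf("InterfaceSeries: %d frames, buried area %.0f..%.0f A^2 (mean %.0f)\n",
              length(x$values), min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Write an interface (or any) series as CSV plus a JSON summary
#' @param series an InterfaceSeries
#' @param csv_path,json_path output paths (NULL to skip either)
#' @export
write_series <- function(series, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(time_ns = series$times, value = series$values)
    if (!is.null(series$windowed)) df$windowed <- series$windowed
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n = length(series$values),
                              mean = mean(series$values),
                              min = min(series$values), max = max(series$values),
                              window_ns = series$window),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

# default distance cutoffs (Angstrom) per contact kind; conventional
# heavy-atom criteria, configurable through contact_spec()
.contact_cutoffs <- c(hbond = 3.5, `salt-bridge` = 4.0, `cation-pi` = 6.0,
                      distance = 4.5)

#' Specification of an inter-subunit contact to monitor
#'
#' @param kind "hbond" (min donor/acceptor N,O distance), "salt-bridge" (min
#'   charged-group N-O distance), "cation-pi" (cation nitrogen to aromatic
#'   ring centroid), or "distance" (min heavy-atom distance)
#' @param sel_a,sel_b lists of [select_atoms()] arguments naming the two atom
#'   groups (e.g. `list(chain="A", resno=194, elety=c("NE2","OE1"))`)
#' @param cutoff distance (Angstrom) below which the contact counts as
#'   satisfied; defaults by kind (3.5 / 4.0 / 6.0 / 4.5)
#' @export
contact_spec <- function(kind = c("hbond", "salt-bridge", "cation-pi", "distance"),
                         sel_a, sel_b, cutoff = NULL) {
  kind <- match.arg(kind)
  if (is.null(cutoff)) cutoff <- .contact_cutoffs[[kind]]
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(kind = kind, sel_a = sel_a, sel_b = sel_b, cutoff = cutoff),
            class = "ContactSpec")
}

.contact_distance <- function(s, spec) {
  ga <- suppressWarnings(do.call(select_atoms, c(list(s, heavy_only = TRUE), spec$sel_a)))
  gb <- suppressWarnings(do.call(select_atoms, c(list(s, heavy_only = TRUE), spec$sel_b)))
  if (!n_atoms(ga) || !n_atoms(gb))
    stop("contact selection resolved to no atoms (",
         if (!n_atoms(ga)) "side A" else "side B", ")")
  xa <- coords(ga); xb <- coords(gb)
  if (spec$kind == "cation-pi") {
    # side B is taken as the aromatic ring: use its centroid
    xb <- matrix(colMeans(xb), ncol = 3)
  }
  if (spec$kind %in% c("hbond", "salt-bridge")) {
    pol <- c("N", "O")
    ka <- ga$atoms$element %in% pol; kb <- gb$atoms$element %in% pol
    if (any(ka)) xa <- xa[ka, , drop = FALSE]
    if (any(kb)) xb <- xb[kb, , drop = FALSE]
  }
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Contact distance/satisfaction over a trajectory
#'
#' @param traj a Trajectory
#' @param spec a [contact_spec()]
#' @return data.frame with `time_ns`, `distance` (Angstrom), `satisfied`
#' @export
contact_series <- function(traj, spec) {
  stopifnot(inherits(traj, "Trajectory"), inherits(spec, "ContactSpec"))
  d <- vapply(seq_len(n_frames(traj)),
              function(i) .contact_distance(frame_structure(traj, i), spec),
              numeric(1))
  data.frame(time_ns = traj$times, distance = d, satisfied = d <= spec$cutoff)
}

#' Contact distance in a single static structure
#' @param s a Structure
#' @param spec a [contact_spec()]
#' @return list with `distance` and `satisfied`
#' @export
contact_measure <- function(s, spec) {
  d <- .contact_distance(s, spec)
  list(distance = d, satisfied = d <= spec$cutoff)
}

#' Dimerization-arm drift over a trajectory
#'
#' Per-frame C-alpha RMSD of an arm region relative to a reference frame,
#' after superposing each frame onto the reference over the partner
#' subunit's anchor region (typically its domain II). The drift therefore
#' measures motion of the arm relative to the binding pocket it sits in, and
#' is invariant to global rigid motion of the whole dimer.
#'
#' @param traj a Trajectory
#' @param arm_chain,arm_resno chain and residue numbers of the arm
#' @param anchor_chain,anchor_resno chain and residue numbers of the partner
#'   anchor region used for superposition
#' @param reference reference frame index (default 1)
#' @return data.frame with `time_ns`, `drift` (Angstrom)
#' @export
arm_drift <- function(traj, arm_chain, arm_resno, anchor_chain, anchor_resno,
                      reference = 1L) {
  stopifnot(inherits(traj, "Trajectory"))
  if (reference < 1 || reference > n_frames(traj))
    stop("reference frame ", reference, " out of range")
  pick <- function(fr, ch, rn) {
    sel <- suppressWarnings(select_atoms(fr, chain = ch, resno = rn, elety = "CA"))
    if (!n_atoms(sel)) stop("selection resolved to no CA atoms")
    coords(sel)
  }
  ref <- frame_structure(traj, reference)
  ref_anchor <- pick(ref, anchor_chain, anchor_resno)
  ref_arm <- pick(ref, arm_chain, arm_resno)
  drift <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_structure(traj, i)
    fit <- kabsch_superpose(pick(fr, anchor_chain, anchor_resno), ref_anchor)
    arm <- apply_transform(fit$transform, pick(fr, arm_chain, arm_resno))
    rmsd(arm, ref_arm)
  }, numeric(1))
  data.frame(time_ns = traj$times, drift = drift)
}
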