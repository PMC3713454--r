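#' Dimer model: a Structure with designated receptor and ligand chains
#'
#' Wraps a Structure containing exactly two receptor subunit chains and 0-2
#' ligand chains, plus a provenance record listing every build step (each
#' superposition with its anchor RMSD).
#'
#' @param structure a Structure
#' @param receptor_chains character vector of exactly 2 chain ids
#' @param ligand_chains character vector of 0-2 chain ids
#' @param provenance list of build-step records
#' @export
new_dimer_model <- function(structure, receptor_chains, ligand_chains = character(),
                            provenance = list()) {
  stopifnot(inherits(structure, "Structure"))
  if (length(receptor_chains) != 2)
    stop("a dimer model needs exactly 2 receptor chains")
  if (length(ligand_chains) > 2) stop("at most 2 ligand chains")
  present <- unique(structure$atoms$chain)
  missing <- setdiff(c(receptor_chains, ligand_chains), present)
  if (length(missing)) stop("chain(s) absent from structure: ",
                            paste(missing, collapse = ", "))
  structure(list(structure = structure, receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains, provenance = provenance),
            class = "DimerModel")
}

#' @export
print.DimerModel <- function(x, ...) {
  cat(sprintf("DimerModel: receptors %s, ligands %s; %d atoms; %d build step(s)\n",
              paste(x$receptor_chains, collapse = "+"),
              if (length(x$ligand_chains)) paste(x$ligand_chains, collapse = "+") else "none",
              n_atoms(x$structure), length(x$provenance)))
  invisible(x)
}

.log_step <- function(model, step, ...) {
  model$provenance <- c(model$provenance, list(c(list(step = step), list(...))))
  model
}

#' Extract one subunit (or ligand) chain of a dimer model as a Structure
#' @param model a DimerModel
#' @param chain chain id
#' @export
dimer_subunit <- function(model, chain) {
  suppressWarnings(select_atoms(model$structure, chain = chain))
}

#' Write a dimer model and its provenance
#' @param model a DimerModel
#' @param path PDB output path; provenance goes to a `.json` sidecar
#' @export
write_dimer_model <- function(model, path) {
  write_structure(model$structure, path)
  jsonlite::write_json(list(receptor_chains = model$receptor_chains,
                            ligand_chains = model$ligand_chains,
                            provenance = model$provenance),
                       sub("\\.pdb$", ".provenance.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

# Paired CA coordinates for an anchor range: template numbering `range` on the
# template chain, donor numbers through `equivalence` (NULL = same numbering).
.anchor_pairs <- function(template_sub, donor, range, equivalence) {
  trange <- intersect(range, unique(template_sub$atoms$resno))
  dnum <- if (is.null(equivalence)) trange
  else suppressWarnings(map_residues(equivalence, trange))
  ok <- !is.na(dnum) & dnum %in% donor$atoms$resno[trimws(donor$atoms$elety) == "CA"] &
    trange %in% template_sub$atoms$resno[trimws(template_sub$atoms$elety) == "CA"]
  list(template = trange[ok], donor = unname(dnum[ok]),
       coverage = sum(ok) / length(range))
}

.ca_coords_for <- function(s, resnos, chain = NULL) {
  a <- s$atoms
  keep <- trimws(a$elety) == "CA" & a$resno %in% resnos
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  rows <- a[keep, , drop = FALSE]
  rows <- rows[match(resnos, rows$resno), , drop = FALSE]
  as.matrix(rows[, c("x", "y", "z")])
}

#' Replace one subunit of a template dimer with a homologous donor monomer
#'
#' The donor is rigidly superposed onto the chosen template subunit over the
#' C-alpha atoms of an anchor range (given in template numbering; the donor
#' equivalents come from an equivalence map), then swapped in for that
#' subunit. This is the core chimera step: the heterodimer geometry is
#' inherited from the template, the subunit's internal geometry from the
#' donor. The other subunit and any ligands are untouched.
#'
#' @param model template DimerModel
#' @param donor donor monomer Structure (single receptor chain)
#' @param anchor_range residue numbers (template numbering) to superpose over;
#'   for ErbB ectodomains the dimerization-critical part of domain II,
#'   residues 240-309 in EGFR numbering, is the conventional choice
#' @param equivalence EquivalenceMap template -> donor numbering (NULL if the
#'   numbering is shared)
#' @param slot chain id of the template subunit to replace (default: first
#'   receptor chain)
#' @param min_coverage minimum fraction of the anchor range that must pair
#'   (default 0.8)
#' @return DimerModel with the donor in place (it inherits the slot chain id);
#'   provenance records the anchor RMSD
#' @export
replace_subunit <- function(model, donor, anchor_range, equivalence = NULL,
                            slot = NULL, min_coverage = 0.8) {
  stopifnot(inherits(model, "DimerModel"), inherits(donor, "Structure"))
  if (is.null(slot)) slot <- model$receptor_chains[1]
  if (!slot %in% model$receptor_chains) stop("slot ", slot, " is not a receptor chain")
  tsub <- dimer_subunit(model, slot)
  pairs <- .anchor_pairs(tsub, donor, anchor_range, equivalence)
  if (pairs$coverage < min_coverage)
    stop(sprintf("anchor coverage %.0f%% below the required %.0f%%",
                 100 * pairs$coverage, 100 * min_coverage))
  fit <- kabsch_superpose(.ca_coords_for(donor, pairs$donor),
                          .ca_coords_for(tsub, pairs$template))
  placed <- set_coords(donor, apply_transform(fit$transform, coords(donor)))
  placed$atoms$chain <- slot
  keep <- model$structure$atoms$chain != slot
  out <- model$structure
  out$atoms <- rbind(out$atoms[keep, , drop = FALSE], placed$atoms)
  rownames(out$atoms) <- NULL
  m2 <- model
  m2$structure <- out
  .log_step(m2, "replace_subunit", slot = slot, donor = donor$id,
            anchor = range(anchor_range), anchor_rmsd = fit$rmsd,
            coverage = pairs$coverage)
}

#' Plan for segment-wise placement of a donor subunit
#'
#' Rigid segments are placed independently; junction residues between
#' consecutive segments are regularized afterwards. Used when the donor's
#' overall conformation (e.g. a bent domain II) differs from the template's
#' so a single rigid fit would be poor.
#'
#' @param donor_ranges list of integer vectors: donor residue numbers per
#'   segment, in order, non-overlapping
#' @param template_ranges list of integer vectors: matching template residue
#'   numbers (same lengths semantics; NULL to reuse `donor_ranges` through the
#'   equivalence map)
#' @export
segment_plan <- function(donor_ranges, template_ranges = NULL) {
  if (!length(donor_ranges)) stop("need at least one segment")
  for (i in seq_along(donor_ranges)[-1]) {
    if (max(donor_ranges[[i - 1]]) >= min(donor_ranges[[i]]))
      stop("segments must be ordered and non-overlapping")
  }
  structure(list(donor_ranges = donor_ranges, template_ranges = template_ranges),
            class = "SegmentPlan")
}

#' Segment-wise subunit replacement
#'
#' Each donor segment is independently superposed (C-alpha Kabsch) onto its
#' template counterpart, so a bent donor can be laid onto a straight template
#' piecewise (the three-segment treatment of a bent domain II). Junction
#' residues (the first residue of each segment after the first) are
#' regularized by placing them at the midpoint of their positions under the
#' two flanking segment transforms; the shift applied is recorded, not
#' minimized.
#'
#' @param model template DimerModel
#' @param donor donor monomer Structure
#' @param plan a [segment_plan()]; ranges are in donor numbering
#' @param equivalence EquivalenceMap donor -> template numbering (NULL if
#'   shared)
#' @param slot template subunit chain to replace
#' @param min_coverage per-segment minimum anchor coverage
#' @return DimerModel; provenance records per-segment anchor RMSDs
#' @export
segmented_replace <- function(model, donor, plan, equivalence = NULL,
                              slot = NULL, min_coverage = 0.8) {
  stopifnot(inherits(model, "DimerModel"), inherits(plan, "SegmentPlan"))
  if (is.null(slot)) slot <- model$receptor_chains[1]
  tsub <- dimer_subunit(model, slot)
  segs <- plan$donor_ranges
  nseg <- length(segs)
  tf <- vector("list", nseg)
  seg_rmsd <- numeric(nseg)
  for (k in seq_len(nseg)) {
    drange <- segs[[k]]
    trange <- if (!is.null(plan$template_ranges)) plan$template_ranges[[k]]
    else if (is.null(equivalence)) drange
    else suppressWarnings(map_residues(equivalence, drange))
    ok <- !is.na(trange) &
      drange %in% donor$atoms$resno[trimws(donor$atoms$elety) == "CA"] &
      trange %in% tsub$atoms$resno[trimws(tsub$atoms$elety) == "CA"]
    if (mean(ok) < min_coverage)
      stop(sprintf("segment %d (%d-%d): anchor coverage %.0f%% below %.0f%%",
                   k, min(drange), max(drange), 100 * mean(ok), 100 * min_coverage))
    fit <- kabsch_superpose(.ca_coords_for(donor, drange[ok]),
                            .ca_coords_for(tsub, unname(trange[ok])))
    tf[[k]] <- fit$transform
    seg_rmsd[k] <- fit$rmsd
  }
  # assemble: residues outside all segments follow the nearest segment's fit
  donor_res <- unique(donor$atoms$resno)
  seg_of <- vapply(donor_res, function(r) {
    k <- which(vapply(segs, function(sg) r >= min(sg) & r <= max(sg), logical(1)))
    if (length(k)) k[1] else {
      mids <- vapply(segs, function(sg) mean(range(sg)), numeric(1))
      which.min(abs(mids - r))
    }
  }, integer(1))
  placed <- donor
  xyz <- coords(donor)
  for (k in seq_len(nseg)) {
    rows <- donor$atoms$resno %in% donor_res[seg_of == k]
    xyz[rows, ] <- apply_transform(tf[[k]], xyz[rows, , drop = FALSE])
  }
  # junction regularization: first residue of each segment k>1 is averaged
  # between its placement under segment k and under segment k-1
  junction_shift <- numeric(0)
  for (k in seq_len(nseg)[-1]) {
    jres <- min(segs[[k]])
    rows <- which(donor$atoms$resno == jres)
    alt <- apply_transform(tf[[k - 1]], coords(donor)[rows, , drop = FALSE])
    shift <- (alt - xyz[rows, , drop = FALSE]) / 2
    xyz[rows, ] <- xyz[rows, , drop = FALSE] + shift
    junction_shift <- c(junction_shift, max(sqrt(rowSums(shift^2))))
  }
  placed <- set_coords(placed, xyz)
  placed$atoms$chain <- slot
  out <- model$structure
  out$atoms <- rbind(out$atoms[out$atoms$chain != slot, , drop = FALSE],
                     placed$atoms)
  rownames(out$atoms) <- NULL
  m2 <- model
  m2$structure <- out
  .log_step(m2, "segmented_replace", slot = slot, donor = donor$id,
            segments = lapply(segs, range), segment_rmsd = seg_rmsd,
            junction_shift_max = if (length(junction_shift)) max(junction_shift) else 0)
}

#' Graft a ligand into a binding site occupied by a template ligand
#'
#' The incoming ligand is superposed onto the bound template ligand over a
#' shared anchor region (e.g. the structurally conserved core of an EGF-family
#' ligand), the template ligand is removed, and the incoming ligand takes its
#' chain id.
#'
#' @param model DimerModel containing the template ligand
#' @param ligand incoming ligand Structure (single chain)
#' @param template_chain chain id of the bound template ligand
#' @param anchor_range residue numbers of the anchor region (template-ligand
#'   numbering)
#' @param equivalence EquivalenceMap template-ligand -> ligand numbering
#'   (NULL if shared)
#' @param min_coverage minimum anchor coverage
#' @return DimerModel with the new ligand in place
#' @export
graft_ligand <- function(model, ligand, template_chain, anchor_range,
                         equivalence = NULL, min_coverage = 0.8) {
  stopifnot(inherits(model, "DimerModel"), inherits(ligand, "Structure"))
  if (!template_chain %in% model$ligand_chains)
    stop("chain ", template_chain, " is not a ligand chain of the model")
  tlig <- dimer_subunit(model, template_chain)
  pairs <- .anchor_pairs(tlig, ligand, anchor_range, equivalence)
  if (pairs$coverage < min_coverage)
    stop(sprintf("ligand anchor coverage %.0f%% below %.0f%%",
                 100 * pairs$coverage, 100 * min_coverage))
  fit <- kabsch_superpose(.ca_coords_for(ligand, pairs$donor),
                          .ca_coords_for(tlig, pairs$template))
  placed <- set_coords(ligand, apply_transform(fit$transform, coords(ligand)))
  placed$atoms$chain <- template_chain
  out <- model$structure
  out$atoms <- rbind(out$atoms[out$atoms$chain != template_chain, , drop = FALSE],
                     placed$atoms)
  rownames(out$atoms) <- NULL
  m2 <- model
  m2$structure <- out
  .log_step(m2, "graft_ligand", chain = template_chain, ligand = ligand$id,
            anchor = range(anchor_range), anchor_rmsd = fit$rmsd)
}

#' Remove a ligand chain from a dimer model
#'
#' Receptor coordinates are untouched (bitwise); the ligand's atoms are
#' dropped and the chain is removed from the model's ligand list.
#'
#' @param model a DimerModel
#' @param chain ligand chain id
#' @export
remove_ligand <- function(model, chain) {
  if (!chain %in% model$ligand_chains)
    stop("chain ", chain, " is not a ligand chain of the model")
  out <- model$structure
  out$atoms <- out$atoms[out$atoms$chain != chain, , drop = FALSE]
  rownames(out$atoms) <- NULL
  m2 <- model
  m2$structure <- out
  m2$ligand_chains <- setdiff(m2$ligand_chains, chain)
  .log_step(m2, "remove_ligand", chain = chain)
}

#' Resolve inter-subunit side-chain clashes by chi-grid search
#'
#' For each residue with side-chain atoms in a steric clash between the two
#' receptor chains, searches a 30-degree grid over chi1 (and chi2 where
#' defined), picking the rotamer that first minimizes the structure-wide
#' inter-subunit clash count and then the deviation from the input
#' conformation. Backbone atoms (and CB) never move. Clashes not involving a
#' rotatable side chain (e.g. backbone-backbone) are reported as residual,
#' never fatal.
#'
#' @param model a DimerModel
#' @param cutoff clash distance in Angstrom (default 2.5)
#' @param step grid step in degrees (default 30)
#' @return DimerModel; provenance records clashes before/after; attribute
#'   `residual_clashes` carries the remaining clash table
#' @export
resolve_clashes <- function(model, cutoff = 2.5, step = 30) {
  stopifnot(inherits(model, "DimerModel"))
  ch <- model$receptor_chains
  backbone <- c("N", "CA", "C", "O", "OXT", "CB")
  clash_table <- function(s) {
    detect_clashes(suppressWarnings(select_atoms(s, chain = ch[1], het = FALSE)),
                   suppressWarnings(select_atoms(s, chain = ch[2], het = FALSE)),
                   cutoff)
  }
  s <- model$structure
  cl <- clash_table(s)
  n0 <- nrow(cl)
  if (!n0) {
    m2 <- .log_step(model, "resolve_clashes", clashes_before = 0L, clashes_after = 0L)
    attr(m2, "residual_clashes") <- cl
    return(m2)
  }
  # candidate residues: clash partners whose clashing atom is a rotatable
  # side-chain atom
  cand <- unique(rbind(
    data.frame(chain = cl$chain_a, resno = cl$resno_a, elety = cl$elety_a),
    data.frame(chain = cl$chain_b, resno = cl$resno_b, elety = cl$elety_b)))
  cand <- cand[!(cand$elety %in% backbone), , drop = FALSE]
  cand <- unique(cand[, c("chain", "resno")])
  angles <- seq(0, 360 - step, by = step)
  for (r in seq_len(nrow(cand))) {
    ref <- residue_ref(cand$chain[r], cand$resno[r])
    rtype <- s$atoms$resid[s$atoms$chain == ref$chain & s$atoms$resno == ref$resno][1]
    nchi <- min(n_chi(rtype), 2L)
    if (!nchi) next
    base_cl <- nrow(clash_table(s))
    if (!base_cl) break
    best <- list(n = base_cl, dev = 0, s = s)
    grid <- if (nchi == 1) lapply(angles, function(a) a)
    else unlist(lapply(angles, function(a) lapply(angles, function(b) c(a, b))),
                recursive = FALSE)
    for (g in grid) {
      s_try <- tryCatch({
        tmp <- set_chi_angle(s, ref, 1, g[1])
        if (length(g) > 1) tmp <- set_chi_angle(tmp, ref, 2, g[2]) else tmp
      }, error = function(e) NULL)
      if (is.null(s_try)) next
      n_try <- nrow(clash_table(s_try))
      dev <- sum(abs((g %% 360 + 180) %% 360 - 180))  # prefer small rotations
      if (n_try < best$n || (n_try == best$n && dev < best$dev)) {
        best <- list(n = n_try, dev = dev, s = s_try)
      }
    }
    s <- best$s
  }
  residual <- clash_table(s)
  m2 <- model
  m2$structure <- s
  m2 <- .log_step(m2, "resolve_clashes", clashes_before = n0,
                  clashes_after = nrow(residual))
  attr(m2, "residual_clashes") <- residual
  m2
}
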