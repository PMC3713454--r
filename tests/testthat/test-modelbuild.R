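# a toy dimer plus a small 3-residue ligand chain docked near subunit A
toy_dimer_with_ligand <- function(n_res = 20) {
  d <- make_toy_dimer(toy_dimer_params(n_res = n_res))
  lig <- new_structure(data.frame(
    chain = "L", resno = 1:3, insert = "", resid = "GLY", elety = "CA",
    element = "C", x = c(-12, -11, -12.5), y = c(10, 13.8, 17.6), z = c(2, 2.8, 1.2),
    stringsAsFactors = FALSE))
  s <- d$structure
  s$atoms <- rbind(s$atoms, lig$atoms)
  new_dimer_model(s, receptor_chains = c("A", "B"), ligand_chains = "L",
                  provenance = d$provenance)
}

test_that("dimer model construction validates its chain roles", {
  d <- toy_dimer_with_ligand()
  expect_s3_class(d, "DimerModel")
  expect_error(new_dimer_model(d$structure, receptor_chains = "A"), "exactly 2")
  expect_error(new_dimer_model(d$structure, receptor_chains = c("A", "Q")),
               "absent")
})

test_that("self-replacement is an exact no-op on coordinates", {
  d <- make_toy_dimer(toy_dimer_params(n_res = 24))
  donor <- dimer_subunit(d, "A")
  out <- replace_subunit(d, donor, anchor_range = 1:24)
  subA <- dimer_subunit(out, "A")
  expect_lt(max(abs(coords(subA) - coords(donor))), 1e-6)
  # untouched partner
  expect_identical(coords(dimer_subunit(out, "B")), coords(dimer_subunit(d, "B")))
  # provenance records the anchor fit
  last <- out$provenance[[length(out$provenance)]]
  expect_equal(last$step, "replace_subunit")
  expect_lt(last$anchor_rmsd, 1e-9)
})

test_that("placement is invariant to the donor's initial pose", {
  d <- make_toy_dimer(toy_dimer_params(bend = 160, n_res = 24))
  donor <- make_toy_arm(150, n_res = 24, sidechains = TRUE)
  set.seed(10)
  tf <- rigid_transform(random_rotation(), rnorm(3, sd = 30))
  donor_moved <- set_coords(donor, apply_transform(tf, coords(donor)))
  out1 <- replace_subunit(d, donor, anchor_range = 12:24, slot = "B")
  out2 <- replace_subunit(d, donor_moved, anchor_range = 12:24, slot = "B")
  expect_lt(max(abs(coords(dimer_subunit(out1, "B")) -
                      coords(dimer_subunit(out2, "B")))), 1e-6)
})

test_that("anchor coverage below threshold is refused", {
  d <- make_toy_dimer(toy_dimer_params(n_res = 24))
  donor <- suppressWarnings(select_atoms(dimer_subunit(d, "A"), resno = 1:10))
  expect_error(replace_subunit(d, donor, anchor_range = 1:24), "coverage")
})

test_that("single-segment plans reduce to whole-body replacement", {
  d <- make_toy_dimer(toy_dimer_params(bend = 170, n_res = 24))
  donor <- make_toy_arm(140, n_res = 24, sidechains = TRUE)
  whole <- replace_subunit(d, donor, anchor_range = 1:24, slot = "A")
  seg <- segmented_replace(d, donor, segment_plan(list(1:24)), slot = "A")
  expect_lt(max(abs(coords(dimer_subunit(whole, "A")) -
                      coords(dimer_subunit(seg, "A")))), 1e-6)
})

test_that("segment-wise placement of a bent donor beats one rigid fit", {
  # straight template arm, strongly bent donor: per-segment fits must be far
  # tighter than the single whole-body fit
  d <- make_toy_dimer(toy_dimer_params(bend = 180, n_res = 25))
  donor <- make_toy_arm(120, n_res = 25, sidechains = TRUE)
  template_ca <- coords(suppressWarnings(
    select_atoms(dimer_subunit(d, "A"), elety = "CA")))
  whole_fit <- kabsch_superpose(coords(suppressWarnings(
    select_atoms(donor, elety = "CA"))), template_ca)   # oracle: one rigid fit
  out <- segmented_replace(d, donor, segment_plan(list(1:12, 13:25)), slot = "A")
  prov <- out$provenance[[length(out$provenance)]]
  expect_equal(prov$step, "segmented_replace")
  expect_length(prov$segment_rmsd, 2)
  expect_lt(max(prov$segment_rmsd), whole_fit$rmsd / 5)
  # junction shift is reported and modest relative to the bend scale
  expect_true(prov$junction_shift_max >= 0)
  expect_error(segmented_replace(d, donor, segment_plan(list(1:12, 13:40)),
                                 slot = "A"), "coverage")
  expect_error(segment_plan(list(1:12, 10:20)), "non-overlapping")
})

test_that("self-grafting a ligand is an exact no-op", {
  d <- toy_dimer_with_ligand()
  lig <- dimer_subunit(d, "L")
  out <- graft_ligand(d, lig, template_chain = "L", anchor_range = 1:3)
  expect_lt(max(abs(coords(dimer_subunit(out, "L")) - coords(lig))), 1e-6)
  expect_error(graft_ligand(d, lig, template_chain = "B", anchor_range = 1:3),
               "not a ligand chain")
  short <- suppressWarnings(select_atoms(lig, resno = 1))
  expect_error(graft_ligand(d, short, template_chain = "L", anchor_range = 1:3),
               "coverage")
})

test_that("grafted ligand clash count matches the all-pairs oracle", {
  d <- toy_dimer_with_ligand()
  # move the incoming ligand somewhere else; grafting must bring it back onto
  # the template pose, so clashes against the receptor are pose-independent
  lig <- dimer_subunit(d, "L")
  set.seed(12)
  lig2 <- set_coords(lig, apply_transform(
    rigid_transform(random_rotation(), c(50, 0, 0)), coords(lig)))
  out <- graft_ligand(d, lig2, template_chain = "L", anchor_range = 1:3)
  recA <- dimer_subunit(out, "A")
  ligP <- dimer_subunit(out, "L")
  got <- detect_clashes(recA, ligP, 4)
  want <- oracle_clashes(coords(recA), coords(ligP), 4)
  expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
})

test_that("ligand removal drops exactly that chain and nothing else", {
  d <- toy_dimer_with_ligand()
  before <- coords(dimer_subunit(d, "A"))
  out <- remove_ligand(d, "L")
  expect_false("L" %in% out$structure$atoms$chain)
  expect_length(out$ligand_chains, 0)
  expect_identical(coords(dimer_subunit(out, "A")), before)
  expect_error(remove_ligand(d, "X"), "not a ligand chain")
})

test_that("interface area is defined on receptor chains only, so ligand removal leaves it unchanged", {
  d <- toy_dimer_with_ligand()
  dm <- toy_domain_map(20)
  area_with <- buried_interface_area(assign_radii(dimer_subunit(d, "A")),
                                     assign_radii(dimer_subunit(d, "B")),
                                     domain_map = dm, points = 240)
  d2 <- remove_ligand(d, "L")
  area_without <- buried_interface_area(assign_radii(dimer_subunit(d2, "A")),
                                        assign_radii(dimer_subunit(d2, "B")),
                                        domain_map = dm, points = 240)
  expect_equal(area_with, area_without)
})

test_that("chi-grid clash resolution clears a rotatable side-chain clash", {
  # chain A: one HIS whose ring points straight into a fixed atom of chain B
  his <- his_residue_structure()
  his$atoms$chain <- "A"
  ne2 <- coords(his)[which(trimws(his$atoms$elety) == "NE2"), ]
  blocker <- new_structure(data.frame(
    chain = "B", resno = 1L, insert = "", resid = "GLY",
    elety = c("CA", "CB"), element = "C",
    x = c(ne2[1] + 8, ne2[1] + 0.8), y = c(ne2[2], ne2[2]),
    z = c(ne2[3], ne2[3]), stringsAsFactors = FALSE))
  s <- his
  s$atoms <- rbind(s$atoms, blocker$atoms)
  m <- new_dimer_model(s, receptor_chains = c("A", "B"))
  n_before <- nrow(detect_clashes(dimer_subunit(m, "A"), dimer_subunit(m, "B"), 2.5))
  expect_gt(n_before, 0)
  fixed <- resolve_clashes(m, cutoff = 2.5)
  residual <- attr(fixed, "residual_clashes")
  expect_equal(nrow(residual), 0)
  # exhaustive-grid oracle: some chi1/chi2 combination must clear it, and
  # backbone atoms must not have moved
  bb <- c("N", "CA", "C", "O", "CB")
  iA <- which(fixed$structure$atoms$chain == "A" &
                trimws(fixed$structure$atoms$elety) %in% bb)
  expect_identical(coords(fixed$structure)[iA, ],
                   coords(m$structure)[iA, ])
})

test_that("clash resolution is a no-op on clash-free models and never worsens", {
  d <- make_toy_dimer(toy_dimer_params(gap = 30, n_res = 16))
  out <- resolve_clashes(d)
  expect_identical(coords(out$structure), coords(d$structure))
  expect_equal(nrow(attr(out, "residual_clashes")), 0)
  # backbone-backbone clash: unresolvable, reported residual, not fatal
  g <- make_toy_dimer(toy_dimer_params(gap = 0, n_res = 16))
  s <- g$structure
  ca_b <- which(s$atoms$chain == "B" & trimws(s$atoms$elety) == "CA" & s$atoms$resno == 8)
  ca_a <- which(s$atoms$chain == "A" & trimws(s$atoms$elety) == "CA" & s$atoms$resno == 8)
  s$atoms[ca_b, c("x", "y", "z")] <- s$atoms[ca_a, c("x", "y", "z")] + c(0.5, 0, 0)
  m <- new_dimer_model(s, receptor_chains = c("A", "B"))
  n0 <- nrow(detect_clashes(dimer_subunit(m, "A"), dimer_subunit(m, "B"), 2.5))
  out2 <- resolve_clashes(m)
  expect_lte(nrow(attr(out2, "residual_clashes")), n0)
  expect_gt(nrow(attr(out2, "residual_clashes")), 0)
})

test_that("model export writes coordinates plus a provenance sidecar", {
  d <- toy_dimer_with_ligand()
  p <- tempfile(fileext = ".pdb")
  write_dimer_model(d, p)
  expect_true(file.exists(p))
  side <- sub("\\.pdb$", ".provenance.json", p)
  expect_true(file.exists(side))
  j <- jsonlite::read_json(side, simplifyVector = TRUE)
  expect_equal(j$receptor_chains, c("A", "B"))
  expect_equal(j$ligand_chains, "L")
})
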