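single_atom <- function(r_elem = "C", x = 0, y = 0, z = 0, chain = "A", resno = 1L) {
  new_structure(data.frame(chain = chain, resno = resno, insert = "",
                           resid = "GLY", elety = "CA", element = r_elem,
                           x = x, y = y, z = z, stringsAsFactors = FALSE))
}

test_that("SASA matches the analytic sphere and is additive when separated", {
  s <- assign_radii(single_atom())         # C: r = 1.7
  got <- sasa(s, probe = 1.4, points = 960)
  expect_equal(got$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  two <- s
  far <- assign_radii(single_atom("O", x = 50, resno = 2L))
  two$atoms <- rbind(s$atoms, far$atoms)
  want <- 4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.52 + 1.4)^2
  expect_lt(abs(sasa(two)$total - want), 0.01 * want)
})

test_that("SASA of two overlapping spheres matches the spherical-cap closed form", {
  r1 <- 1.7 + 1.4; r2 <- 1.52 + 1.4
  for (d in c(1.0, 2.0, 3.0, 4.0)) {
    s <- assign_radii(single_atom("C"))
    o <- assign_radii(single_atom("O", x = d, resno = 2L))
    s$atoms <- rbind(s$atoms, o$atoms)
    got <- sasa(s, points = 960)$total
    want <- oracle_two_sphere_sasa(r1, r2, d)
    expect_lt(abs(got - want), 0.015 * want,
              label = sprintf("two-sphere SASA at d=%.1f vs closed form", d))
  }
})

test_that("doubling the quadrature density changes SASA by under 0.5%", {
  su <- toy_subunits(toy_dimer_params(n_res = 16))
  a1 <- sasa(su$a, points = 960)$total
  a2 <- sasa(su$a, points = 1920)$total
  expect_lt(abs(a2 - a1) / a2, 0.005)
})

test_that("SASA demands assigned radii and names the offending atom", {
  s <- single_atom()
  expect_error(sasa(s), "assign_radii")
  expect_error(sasa(assign_radii(single_atom("XX"), fallback = NA)), "XX")
  r <- load_radii()
  expect_equal(r[["C"]], 1.70)
  expect_equal(r[["N"]], 1.55)
})

test_that("buried area is symmetric, non-negative, and zero at separation", {
  su <- toy_subunits(toy_dimer_params(n_res = 20))
  ab <- buried_interface_area(su$a, su$b, domain_map = su$map, points = 480)
  ba <- buried_interface_area(su$b, su$a, domain_map = su$map, points = 480)
  expect_equal(ab, ba, tolerance = 1e-9)
  expect_gt(ab, 0)
  far <- set_coords(su$b, sweep(coords(su$b), 2, c(100, 0, 0), "+"))
  expect_equal(buried_interface_area(su$a, far, domain_map = su$map, points = 480),
               0, tolerance = 0.1)
  expect_error(buried_interface_area(su$a, suppressWarnings(
    select_atoms(su$b, chain = "Q")), domain_map = su$map), "non-empty")
})

test_that("buried area falls monotonically as subunits translate apart", {
  su <- toy_subunits(toy_dimer_params(n_res = 20))
  areas <- vapply(c(0, 0.5, 1, 1.5, 2), function(dx) {
    moved <- set_coords(su$b, sweep(coords(su$b), 2, c(dx, 0, 0), "+"))
    buried_interface_area(su$a, moved, domain_map = su$map, points = 480)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  # and far enough apart the interface is gone entirely
  gone <- set_coords(su$b, sweep(coords(su$b), 2, c(12, 0, 0), "+"))
  expect_equal(buried_interface_area(su$a, gone, domain_map = su$map,
                                     points = 480), 0, tolerance = 0.1)
})

test_that("domain restriction counts only the requested domains", {
  su <- toy_subunits(toy_dimer_params(n_res = 30))
  all3 <- buried_interface_area(su$a, su$b, domain_map = su$map, points = 480)
  only1 <- buried_interface_area(su$a, su$b, restrict = "I",
                                 domain_map = su$map, points = 480)
  unrestricted <- buried_interface_area(su$a, su$b, restrict = NULL, points = 480)
  expect_lt(only1, all3)
  expect_equal(all3, unrestricted, tolerance = 1e-9)  # toy map spans everything
  expect_error(buried_interface_area(su$a, su$b, restrict = "V",
                                     domain_map = su$map, points = 480), "absent")
})

test_that("window averaging equals the brute-force mean and closed forms", {
  t <- seq(0, 480, by = 20)
  expect_equal(window_average(rep(7, length(t)), t, 200), rep(7, length(t)))
  ramp <- 3 * t + 2
  got <- window_average(ramp, t, 200)
  inner <- t >= 100 & t <= 380          # symmetric windows in the interior
  expect_equal(got[inner], ramp[inner], tolerance = 1e-12)
  set.seed(21)
  v <- rnorm(length(t))
  expect_equal(window_average(v, t, 200), oracle_window_average(v, t, 200),
               tolerance = 1e-12)
  expect_error(window_average(v, t, 0), "window")
  expect_error(window_average(v, rev(t), 200), "increasing")
})

test_that("interface series: constant, single-frame, and trend cases", {
  p0 <- toy_dimer_params(gap = 0, n_res = 14)
  dm <- toy_domain_map(14)
  const <- make_pseudo_trajectory(pseudo_trajectory_params(p0, p0, n_frames = 4,
                                                           noise_sd = 0))
  ser <- interface_series(const, "A", "B", domain_map = dm, points = 240,
                          window = 200)
  expect_equal(diff(range(ser$values)), 0, tolerance = 1e-9)
  expect_equal(ser$windowed, ser$values, tolerance = 1e-9)
  single <- make_pseudo_trajectory(pseudo_trajectory_params(p0, p0, n_frames = 1,
                                                            noise_sd = 0))
  s1 <- interface_series(single, "A", "B", domain_map = dm, points = 240)
  d <- make_toy_dimer(p0)
  static <- buried_interface_area(assign_radii(dimer_subunit(d, "A")),
                                  assign_radii(dimer_subunit(d, "B")),
                                  domain_map = dm, points = 240)
  expect_length(s1$values, 1)
  expect_equal(s1$values, static, tolerance = 1e-9)
  opening <- make_pseudo_trajectory(pseudo_trajectory_params(
    p0, toy_dimer_params(gap = 6, n_res = 14), n_frames = 10, noise_sd = 0))
  ser2 <- interface_series(opening, "A", "B", domain_map = dm, points = 240,
                           window = 60)
  expect_true(all(diff(ser2$windowed) < 0))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_series(ser2, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 10)
  expect_equal(jsonlite::read_json(js)$n, 10)
})

test_that("contact kinds and cutoffs behave on constructed geometries", {
  # donor N and acceptor O fixed 2.9 apart: hydrogen bond satisfied
  pair <- new_structure(data.frame(
    chain = c("A", "B"), resno = 1L, insert = "", resid = c("GLN", "SER"),
    elety = c("NE2", "OG"), element = c("N", "O"),
    x = c(0, 2.9), y = 0, z = 0, stringsAsFactors = FALSE))
  hb <- contact_spec("hbond", list(chain = "A"), list(chain = "B"))
  expect_equal(hb$cutoff, 3.5)
  got <- contact_measure(pair, hb)
  expect_equal(got$distance, 2.9)
  expect_true(got$satisfied)
  # same pair at 8 A fails every kind
  far <- set_coords(pair, cbind(c(0, 8), 0, 0))
  for (k in c("hbond", "salt-bridge", "cation-pi", "distance")) {
    sp <- contact_spec(k, list(chain = "A"), list(chain = "B"))
    expect_false(contact_measure(far, sp)$satisfied)
  }
  # cation-pi measures to the ring centroid, not the nearest ring atom
  ring <- new_structure(data.frame(
    chain = "B", resno = 2L, insert = "", resid = "TYR",
    elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), element = "C",
    x = 5 + 1.4 * cos(seq(0, 5) * pi / 3), y = 1.4 * sin(seq(0, 5) * pi / 3),
    z = 0, stringsAsFactors = FALSE))
  cat_n <- new_structure(data.frame(
    chain = "A", resno = 1L, insert = "", resid = "ARG", elety = "NH1",
    element = "N", x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  s <- cat_n; s$atoms <- rbind(s$atoms, ring$atoms)
  cp <- contact_spec("cation-pi", list(chain = "A"), list(chain = "B"))
  expect_equal(contact_measure(s, cp)$distance, 5, tolerance = 1e-9)
  expect_error(contact_spec("hbond", list(), list(), cutoff = -1), "cutoff")
})

test_that("contact series tracks a separating pseudo-trajectory", {
  p0 <- toy_dimer_params(gap = 0, n_res = 12)
  p1 <- toy_dimer_params(gap = 20, n_res = 12)
  tr <- make_pseudo_trajectory(pseudo_trajectory_params(p0, p1, n_frames = 6,
                                                        noise_sd = 0))
  sp <- contact_spec("distance", list(chain = "A", resno = 3),
                     list(chain = "B", resno = 3), cutoff = 5)
  cs <- contact_series(tr, sp)
  expect_equal(nrow(cs), 6)
  expect_true(all(diff(cs$distance) > 0))
  expect_true(cs$satisfied[1])
  expect_false(cs$satisfied[6])
  bad <- contact_spec("distance", list(chain = "Z"), list(chain = "B"))
  expect_error(contact_series(tr, bad), "no atoms")
})

test_that("arm drift is zero for static motion and rigid-invariant", {
  p0 <- toy_dimer_params(gap = 0, n_res = 16)
  static <- make_pseudo_trajectory(pseudo_trajectory_params(p0, p0, n_frames = 5,
                                                            noise_sd = 0))
  ad <- arm_drift(static, "B", 1:8, "A", 1:16)
  expect_equal(ad$drift, rep(0, 5), tolerance = 1e-9)
  # arm displaced linearly (gap growth) -> drift grows monotonically
  moving <- make_pseudo_trajectory(pseudo_trajectory_params(
    p0, toy_dimer_params(gap = 10, n_res = 16), n_frames = 5, noise_sd = 0))
  ad2 <- arm_drift(moving, "B", 1:8, "A", 1:16)
  expect_equal(ad2$drift[1], 0, tolerance = 1e-9)
  expect_true(all(diff(ad2$drift) > 0))
  # applying one global rigid transform to every frame changes nothing
  set.seed(31)
  tf <- rigid_transform(random_rotation(), rnorm(3, sd = 20))
  moved <- moving
  for (i in seq_len(nrow(moved$xyz))) {
    m <- matrix(moved$xyz[i, ], ncol = 3, byrow = TRUE)
    moved$xyz[i, ] <- as.vector(t(apply_transform(tf, m)))
  }
  ad3 <- arm_drift(moved, "B", 1:8, "A", 1:16)
  expect_equal(ad3$drift, ad2$drift, tolerance = 1e-6)
  expect_error(arm_drift(moving, "B", 1:8, "A", 1:16, reference = 9), "out of range")
})
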