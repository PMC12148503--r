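test_that("sulfur placement honours bond length, angle and torsion", {
  site <- dimer_sites(make_ideal_cysteine())[[1]]
  p <- sweep_params()
  for (chi in seq(-179, 180, by = 1)) {
    s <- place_sulfur(site, chi, p)
    expect_equal(vlen(s - site$cb), p$bond_length, tolerance = 1e-9)
    expect_equal(bond_angle(site$ca, site$cb, s), p$bond_angle,
                 tolerance = 1e-9)
    expect_equal(wrap_angle(torsion_angle(site$n, site$ca, site$cb, s) -
                              chi), 0, tolerance = 1e-6)
  }
})

test_that("placement round-trips chi1 over random site geometries", {
  set.seed(101)
  p <- sweep_params()
  worst <- 0
  for (i in 1:10000) {
    tf <- rigid_transform(cystinescan:::random_rotation(),
                          stats::rnorm(3, sd = 20))
    site <- cystinescan:::transform_site(
      dimer_sites(make_ideal_cysteine())[[1]], tf)
    chi <- stats::runif(1, -180, 180)
    s <- place_sulfur(site, chi, p)
    worst <- max(worst,
                 abs(wrap_angle(torsion_angle(site$n, site$ca, site$cb, s) -
                                  chi)),
                 abs(vlen(s - site$cb) - p$bond_length) * 1e3,
                 abs(bond_angle(site$ca, site$cb, s) - p$bond_angle) * 1e3)
  }
  expect_lt(worst, 1e-6)
})

test_that("sweep positions lie on the rotamer circle at the grid size", {
  site <- dimer_sites(make_ideal_cysteine())[[1]]
  pr <- sweep_positions(site)
  expect_equal(length(pr$angles), 360)
  expect_equal(pr$angles[1], -179)
  expect_equal(pr$angles[360], 180)
  circ <- cystinescan:::sulfur_circle(site)
  rad <- apply(pr$pos, 1, function(s) {
    v <- s - circ$center
    vlen(v - sum(v * circ$axis) * circ$axis)
  })
  expect_lt(max(abs(rad - circ$radius)), 1e-9)
  pr5 <- sweep_positions(site, sweep_params(step = 5))
  expect_equal(length(pr5$angles), 72)
})

test_that("clash masks match the naive overlap oracle", {
  m <- feasible_dimer()
  sites <- dimer_sites(m)
  m2 <- add_clash_probe(m, sites[[1]], 40, 10)
  pr <- clash_scan(sweep_positions(sites[[1]]), m2)
  expect_equal(pr$clash, oracle_clash(pr, m2))
  # the marked arc is contiguous around 40 within one grid step
  hit <- pr$angles[pr$clash]
  expect_equal(range(hit), c(30, 50))
  # nothing to clash with: site alone in space
  lone <- make_ideal_cysteine()
  pr0 <- clash_scan(sweep_positions(dimer_sites(lone)[[1]]), lone)
  expect_false(any(pr0$clash))
})

test_that("cross-distance minima equal the exhaustive oracle exactly", {
  m <- feasible_dimer()
  sites <- dimer_sites(m)
  pa <- sweep_positions(sites[[1]])
  pb <- sweep_positions(sites[[2]])
  pa <- min_cross_distances(pa, pb)
  ora <- oracle_min_cross(pa, pb)
  expect_equal(pa$min_cross, ora$min, tolerance = 1e-12)
  expect_equal(pa$partner_angle, ora$argmin)
  # C2 symmetry of the construction: D(a,b) = D(b,a)
  D <- cystinescan:::cross_distance_matrix(pa, pb)
  expect_equal(D, t(D), tolerance = 1e-9)
  # grid refinement moves minima by less than the circle-arc Lipschitz bound
  fine <- sweep_params(step = 0.1)
  pa_f <- min_cross_distances(sweep_positions(sites[[1]], fine),
                              sweep_positions(sites[[2]], fine))
  expect_lt(abs(min(pa_f$min_cross) - min(pa$min_cross)), 0.06)
})

test_that("feasibility recovers the engineered pair and verdicts", {
  m <- feasible_dimer(2.05, -120, block_rest = TRUE)
  sites <- dimer_sites(m)
  sc <- accessibility_scan(sites[[1]], sites[[2]], m)
  expect_true(sc$result$any_feasible)
  expect_equal(nrow(sc$result$feasible_pairs), 1)
  expect_equal(sc$result$best_pair$theta_a, -120)
  expect_equal(sc$result$best_pair$theta_b, -120)
  expect_equal(sc$result$best_pair$distance, 2.05, tolerance = 1e-9)
  pa <- sc$result$per_angle
  expect_true(pa$feasible[pa$angle == -120])
  expect_equal(sum(pa$feasible), 1)
})

test_that("an out-of-reach dimer is infeasible by the triangle inequality", {
  m <- make_c2_dimer(dimer_spec(cb_separation = 30))
  sites <- dimer_sites(m)
  sc <- accessibility_scan(sites[[1]], sites[[2]], m)
  expect_false(sc$result$any_feasible)
  expect_null(sc$result$best_pair)
  expect_gt(min(sc$profile_a$min_cross), 2.1)
})

test_that("deepening the overlap requirement never adds clashes and widening the distance band never removes feasible pairs", {
  m <- feasible_dimer()
  sites <- dimer_sites(m)
  m2 <- add_clash_probe(m, sites[[1]], -90, 60)
  base <- sweep_positions(sites[[1]])
  n_clash <- vapply(c(0.2, 0.4, 0.6, 0.8), function(ov) {
    sum(clash_scan(base, m2, sweep_params(clash_overlap = ov))$clash)
  }, numeric(1))
  expect_true(all(diff(n_clash) <= 0))
  pa <- clash_scan(sweep_positions(sites[[1]]), m)
  pb <- clash_scan(sweep_positions(sites[[2]]), m)
  sizes <- vapply(c(0.05, 0.1, 0.2, 0.4), function(tol) {
    nrow(feasibility(pa, pb, sweep_params(ss_tolerance = tol))$feasible_pairs)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_gt(sizes[4], sizes[1])
})

test_that("scans are equivariant under rigid motion of the whole model", {
  m <- feasible_dimer(2.05, -120, block_rest = TRUE)
  tf <- rigid_transform(rot_y(33) %*% rot_x(-12), c(5, -3, 7))
  m2 <- transform_model(m, tf)
  r1 <- local({
    s <- dimer_sites(m); accessibility_scan(s[[1]], s[[2]], m)
  })
  r2 <- local({
    s <- dimer_sites(m2); accessibility_scan(s[[1]], s[[2]], m2)
  })
  expect_equal(r1$profile_a$clash, r2$profile_a$clash)
  expect_equal(r1$profile_a$min_cross, r2$profile_a$min_cross,
               tolerance = 1e-9)
  expect_equal(r1$result$feasible_pairs, r2$result$feasible_pairs,
               tolerance = 1e-9)
})

test_that("registration shifts modulate feasibility as the oracle predicts", {
  m <- feasible_dimer(2.05, -120, block_rest = TRUE)
  sites <- dimer_sites(m)
  idn <- rigid_transform()
  away <- rigid_transform(t = c(10, 0, 0))  # protomer B straight away from A
  res <- registration_shift_scan(sites[[1]], sites[[2]], m,
                                 list(idn, away))
  plain <- accessibility_scan(sites[[1]], sites[[2]], m)$result
  expect_equal(res[[1]]$result$feasible_pairs, plain$feasible_pairs)
  expect_false(res[[2]]$result$any_feasible)
  # infeasible at identity, feasible after a solved lateral shift
  m_far <- feasible_dimer(2.45, -120, block_rest = TRUE)
  sfar <- dimer_sites(m_far)
  base <- accessibility_scan(sfar[[1]], sfar[[2]], m_far)$result
  expect_false(base$any_feasible)
  # the engineered approach is along x: pull B back by the excess distance
  fix <- rigid_transform(t = c(-0.40, 0, 0))
  res2 <- registration_shift_scan(sfar[[1]], sfar[[2]], m_far,
                                  list(idn, fix))
  expect_false(res2[[1]]$result$any_feasible)
  expect_true(res2[[2]]$result$any_feasible)
  # oracle confirmation on the shifted model
  m_shift <- transform_model(m_far, fix, chains = "B")
  s_shift <- cystinescan:::transform_site(sfar[[2]], fix)
  pa <- clash_scan(sweep_positions(sfar[[1]]), m_shift)
  pb <- clash_scan(sweep_positions(s_shift), m_shift)
  free_a <- pa$angles[!pa$clash]
  free_b <- pb$angles[!pb$clash]
  D <- cystinescan:::cross_distance_matrix(pa, pb)
  ok <- D[match(free_a, pa$angles), match(free_b, pb$angles), drop = FALSE]
  expect_equal(sort(res2[[2]]$result$feasible_pairs$distance),
               sort(ok[ok <= 2.1]), tolerance = 1e-12)
  expect_error(registration_shift_scan(sites[[1]], sites[[2]], m, list()),
               "empty")
})

test_that("sweep TSV and pseudoatom exports are readable", {
  m <- feasible_dimer()
  sites <- dimer_sites(m)
  pr <- min_cross_distances(clash_scan(sweep_positions(sites[[1]]), m),
                            sweep_positions(sites[[2]]))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(pr, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 360)
  expect_equal(min(back$min_cross), 2.05, tolerance = 1e-9)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pseudoatoms(pr, f2)
  ps <- read_structure(f2)
  expect_equal(nrow(ps$atoms), 360)
  expect_true(all(ps$atoms$resid == "PSS"))
})
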