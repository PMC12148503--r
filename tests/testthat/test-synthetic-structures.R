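test_that("ideal cysteine builds are deterministic and well-formed", {
  a <- make_ideal_cysteine(chi1 = -60)
  b <- make_ideal_cysteine(chi1 = -60)
  expect_identical(a$atoms, b$atoms)
  sites <- find_cysteines(a)
  expect_length(sites, 1)
  s <- sites[[1]]
  expect_equal(torsion_angle(s$n, s$ca, s$cb, s$sg), -60, tolerance = 1e-6)
  g <- cystinescan:::IDEAL_GEOM
  expect_equal(vlen(s$n - s$ca), g$n_ca, tolerance = 1e-9)
  expect_equal(vlen(s$cb - s$ca), g$ca_cb, tolerance = 1e-9)
  expect_equal(bond_angle(s$n, s$ca, s$cb), g$n_ca_cb, tolerance = 1e-9)
})

test_that("C2 dimer respects its spec", {
  spec <- dimer_spec(cb_separation = 6.5)
  m <- make_c2_dimer(spec)
  sites <- dimer_sites(m)
  expect_length(sites, 2)
  expect_equal(vlen(sites[[1]]$cb - sites[[2]]$cb), 6.5, tolerance = 1e-9)
  # two-fold about z reproduces protomer B exactly (no twist/offset)
  a <- as.matrix(m$atoms[m$atoms$chain == "A", c("x", "y", "z")])
  b <- as.matrix(m$atoms[m$atoms$chain == "B", c("x", "y", "z")])
  expect_lt(max(abs(apply_transform(rigid_transform(rot_z(180)), a) - b)),
            1e-9)
  # lateral offset shifts protomer B along y only
  m2 <- make_c2_dimer(dimer_spec(cb_separation = 6.5, lateral_offset = 0.5))
  b2 <- as.matrix(m2$atoms[m2$atoms$chain == "B", c("x", "y", "z")])
  expect_equal(b2 - b, matrix(rep(c(0, 0.5, 0), each = nrow(b)), ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the engineered closest approach is unique and exact", {
  params <- sweep_params()
  m <- make_c2_dimer(dimer_spec_for_min_distance(2.05, -120, params))
  sites <- dimer_sites(m)
  pa <- sweep_positions(sites[[1]], params)
  pb <- sweep_positions(sites[[2]], params)
  D <- cystinescan:::cross_distance_matrix(pa, pb)
  expect_equal(min(D), 2.05, tolerance = 1e-9)
  k <- arrayInd(which.min(D), dim(D))
  expect_equal(pa$angles[k[1]], -120)
  expect_equal(pb$angles[k[2]], -120)
  expect_equal(sum(abs(D - 2.05) < 1e-9), 1)  # unique attaining pair
})

test_that("a too-small separation is a construction error", {
  expect_error(make_c2_dimer(dimer_spec(cb_separation = 2)),
               "margin|interpenetrate")
})

test_that("conflicting quintet and separation is a stated obstruction", {
  expect_error(
    make_c2_dimer(dimer_spec(cb_separation = 10,
                             target_quintet = c(-60, -80, -90, -80, -60))),
    "separation")
})

test_that("clash probes carve the requested arc and only that arc", {
  m <- feasible_dimer()
  sites <- dimer_sites(m)
  cases <- list(c(40, 10), c(-120, 25), c(170, 15))  # last wraps across 180
  for (cs in cases) {
    m2 <- add_clash_probe(m, sites[[1]], cs[1], cs[2])
    pr <- clash_scan(sweep_positions(sites[[1]]), m2)
    expect_equal(pr$clash, oracle_clash(pr, m2))
    want <- abs(wrap_angle(pr$angles - cs[1])) <= cs[2]
    expect_lte(sum(pr$clash != want), 2)  # within one grid step per edge
  }
  # halfwidth 0: probe just inside threshold marks a single angle
  m3 <- add_clash_probe(m, sites[[1]], 40, 0)
  pr3 <- clash_scan(sweep_positions(sites[[1]]), m3)
  expect_equal(pr3$angles[pr3$clash], 40)
  # probe beyond every cone point's reach: no clashes
  m4 <- m
  m4$atoms <- rbind(m4$atoms, cystinescan:::cys_atom_row(
    "X", 900, "CP", "C", sites[[1]]$cb + c(0, 0, 50), "PRB"))
  pr4 <- clash_scan(sweep_positions(sites[[1]]), m4)
  expect_false(any(pr4$clash))
  expect_error(add_clash_probe(m, sites[[1]], 0, 180), "arc_halfwidth")
})

test_that("dihedral ensembles are seeded, reproducible and well-shaped", {
  s1 <- sample_dihedral_ensemble(ensemble_spec(500, seed = 9))
  s2 <- sample_dihedral_ensemble(ensemble_spec(500, seed = 9))
  expect_identical(s1, s2)
  s3 <- sample_dihedral_ensemble(ensemble_spec(500, seed = 10))
  expect_false(identical(s1$chi3, s3$chi3))
  expect_equal(nrow(sample_dihedral_ensemble(ensemble_spec(0))), 0)
  expect_true(all(s1$chi3 > -180 & s1$chi3 <= 180))
  expect_error(ensemble_spec(10, components = list(
    chi3 = data.frame(mean = 0, sd = 5, weight = 0.5))), "sum to 1")
})

test_that("ensemble component means are recovered (parameter recovery)", {
  n <- 10000
  recs <- sample_dihedral_ensemble(ensemble_spec(n, seed = 1))
  chi3 <- recs$chi3
  up <- chi3[chi3 > 0]
  dn <- chi3[chi3 <= 0]
  # 3 standard errors of the component mean, sd = 8, n ~ n/2
  tol <- 3 * 8 / sqrt(n / 2)
  expect_lt(abs(mean(up) - 95), tol)
  expect_lt(abs(mean(dn) - (-87)), tol)
})

test_that("empty models write header-only fixtures that re-parse", {
  m <- make_ideal_cysteine()
  m$atoms <- m$atoms[0, ]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(m, f)
  lines <- readLines(f)
  expect_true(any(grepl("^HEADER", lines)))
  expect_false(any(grepl("^ATOM", lines)))
  m2 <- make_c2_dimer(dimer_spec(cb_separation = 6))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(m2, f2)
  expect_length(find_cysteines(read_structure(f2)), 2)
})
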