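test_that("fixture write/read round-trips coordinates at PDB precision", {
  m <- make_ideal_cysteine(chi1 = -60)
  m$resolution <- 1.8
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), 6)
  expect_equal(m2$resolution, 1.8)
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                      as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3)
  # second round trip is exact (coordinates already quantised)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(m2, f2)
  m3 <- read_structure(f2)
  expect_identical(as.matrix(m3$atoms[, c("x", "y", "z")]),
                   as.matrix(m2$atoms[, c("x", "y", "z")]))
})

test_that("mmCIF path parses atoms and resolution", {
  m <- make_ideal_cysteine()
  f <- withr::local_tempfile(fileext = ".cif")
  write_min_cif(f, m$atoms, res_high = 1.9)
  m2 <- read_structure(f)
  expect_equal(m2$source_format, "mmcif")
  expect_equal(m2$resolution, 1.9)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(length(find_cysteines(m2)), 1)
})

test_that("unreadable input and unknown formats raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(read_structure(f), "parse")
  expect_error(read_structure(tempfile(fileext = ".xyz")), "")
  f2 <- withr::local_tempfile(fileext = ".weird")
  writeLines("x", f2)
  expect_error(read_structure(f2), "format")
})

test_that("zero-cysteine model is valid and yields no sites", {
  m <- make_ideal_cysteine()
  m$atoms$resid <- "ALA"
  m$atoms <- m$atoms[m$atoms$elety != "SG", ]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(m, f)
  expect_length(find_cysteines(read_structure(f)), 0)
})

test_that("altloc resolution keeps highest occupancy, label order on ties", {
  m <- make_ideal_cysteine(chi1 = -60)
  sg <- m$atoms$elety == "SG"
  alt <- m$atoms[sg, ]
  alt$altloc <- "B"; alt$occ <- 0.4; alt$x <- alt$x + 1
  m$atoms$altloc[sg] <- "A"; m$atoms$occ[sg] <- 0.6
  m$atoms <- rbind(m$atoms, alt)
  r <- select_altloc(m)
  expect_equal(sum(r$atoms$elety == "SG"), 1)
  expect_equal(r$atoms$altloc[r$atoms$elety == "SG"], "A")
  # tie at 0.5/0.5: lexicographically first altloc wins
  m$atoms$occ[m$atoms$elety == "SG"] <- 0.5
  r2 <- select_altloc(m)
  expect_equal(r2$atoms$altloc[r2$atoms$elety == "SG"], "A")
  # no-altloc input is identity
  m0 <- make_ideal_cysteine()
  expect_identical(select_altloc(m0)$atoms, m0$atoms)
})

test_that("cysteines missing anchor atoms are excluded with a warning", {
  m <- make_ideal_cysteine(chi1 = -60)
  m$atoms <- m$atoms[m$atoms$elety != "CB", ]
  expect_warning(sites <- find_cysteines(m), "excluded")
  expect_length(sites, 0)
})

test_that("disulfide detection partitions sites into pairs and free", {
  # bonded pair from the quintet builder plus one distant free cysteine
  qd <- make_c2_dimer(dimer_spec(target_quintet = c(-60, -80, -90, -80, -60)))
  far <- make_ideal_cysteine(origin = c(40, 0, 0), chain = "C", resno = 7,
                             chi1 = 60)
  qd$atoms <- rbind(qd$atoms, far$atoms)
  det <- detect_disulfides(find_cysteines(qd))
  expect_length(det$pairs, 1)
  expect_equal(det$pairs[[1]]$ss_distance, 2.05, tolerance = 1e-9)
  expect_true(det$pairs[[1]]$interchain)
  free <- vapply(det$sites, function(s) s$is_free, logical(1))
  expect_equal(sum(!free), 2)   # exactly the bonded pair
  expect_equal(sum(free), 1)
  # symmetry: permuting site order never changes the pair set
  det2 <- detect_disulfides(rev(find_cysteines(qd)))
  keyset <- function(d) sort(vapply(d$pairs, function(p)
    paste(sort(c(p$site_a$key, p$site_b$key)), collapse = "+"), ""))
  expect_identical(keyset(det2), keyset(det))
})

test_that("disulfide threshold separates bonded from free", {
  two <- function(dx) {
    a <- make_ideal_cysteine(chain = "A", chi1 = -60)
    b <- make_ideal_cysteine(origin = c(dx, 0, 0), chain = "B", chi1 = -60)
    a$atoms <- rbind(a$atoms, b$atoms)
    a
  }
  sga <- function(m) m$atoms[m$atoms$elety == "SG" & m$atoms$chain == "A", ]
  # translate chain B so the SG-SG distance is exactly the probe value
  probe_at <- function(d) {
    m <- two(0)
    sg <- m$atoms$elety == "SG"
    shift <- d - 0
    bsel <- m$atoms$chain == "B"
    off <- m$atoms$x[sg & bsel] - m$atoms$x[sg & !bsel]
    m$atoms$x[bsel] <- m$atoms$x[bsel] - off + d
    m
  }
  det <- detect_disulfides(find_cysteines(probe_at(2.05)))
  expect_length(det$pairs, 1)
  det2 <- detect_disulfides(find_cysteines(probe_at(3.5)))
  expect_length(det2$pairs, 0)
  expect_true(all(vapply(det2$sites, function(s) s$is_free, logical(1))))
})

test_that("measure_distance handles singles, sets, symmetry and errors", {
  at <- rbind(
    cystinescan:::cys_atom_row("A", 1, "CA", "C", c(0, 0, 0), "GLY"),
    cystinescan:::cys_atom_row("B", 2, "CA", "C", c(3, 4, 0), "GLY"),
    cystinescan:::cys_atom_row("B", 2, "CB", "C", c(10, 0, 0), "ALA"))
  m <- structure_model(at)
  expect_equal(measure_distance(m, "A:1:CA", "B:2:CA"), 5.00)
  expect_equal(measure_distance(m, "B:2:CA", "A:1:CA"),
               measure_distance(m, "A:1:CA", "B:2:CA"))
  expect_equal(measure_distance(m, "A:1:CA", "B:2:C*",
                                mode = "min_over_set"), 5.00)
  expect_error(measure_distance(m, "A:1:CA", "B:2:C*"), "single")
  expect_error(measure_distance(m, "A:9:CA", "B:2:CA"), "matches no atoms")
})
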