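# Synthetic-structure generator: every scan, survey and i/o stage is
# testable against inputs built here, with geometry known in closed form.

# Ideal covalent geometry used for generated cysteines (Angstrom, degrees).
# The exact values only set absolute coordinates; no invariant depends on
# them beyond the CA-CB sanity band.
IDEAL_GEOM <- list(n_ca = 1.458, ca_cb = 1.530, n_ca_cb = 110.5,
                   ca_c = 1.525, n_ca_c = 111.2, c_o = 1.231,
                   ca_c_o = 120.5, cb_s = 1.81, ca_cb_s = 114.3,
                   s_s = 2.05, cb_s_s = 104.15)

cys_atom_row <- function(chain, resno, elety, element, pos, resid = "CYS") {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = element, altloc = "", occ = 1, b = 0,
             x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
}

#' Build an ideal cysteine residue
#'
#' N, CA, CB plus backbone C and O at ideal internal coordinates
#' (N-CA 1.458 A, CA-CB 1.530 A, N-CA-CB 110.5 deg), optionally with SG
#' placed at a requested chi1 via the same internal-coordinate engine as
#' the sweep. Deterministic: identical inputs give bit-identical
#' coordinates.
#'
#' @param origin length-3 translation applied after `orientation`.
#' @param orientation 3x3 rotation applied to the canonical local frame.
#' @param chain,resno residue identifiers.
#' @param chi1 optional torsion (degrees) at which to build SG.
#' @param params [sweep_params()] supplying the CB-S length and CA-CB-S
#'   angle for SG placement.
#' @return a [structure_model()] holding the one residue.
#' @export
make_ideal_cysteine <- function(origin = c(0, 0, 0), orientation = diag(3),
                                chain = "A", resno = 1, chi1 = NULL,
                                params = sweep_params()) {
  g <- IDEAL_GEOM
  ca <- c(0, 0, 0)
  n <- c(g$n_ca, 0, 0)
  th <- deg2rad(g$n_ca_cb)
  cb <- g$ca_cb * c(cos(th), sin(th), 0)
  cc <- place_internal(cb, n, ca, g$ca_c, g$n_ca_c, -120)
  oo <- place_internal(n, ca, cc, g$c_o, g$ca_c_o, 0)
  tf <- rigid_transform(orientation, origin)
  rows <- rbind(
    cys_atom_row(chain, resno, "N", "N", apply_transform(tf, n)),
    cys_atom_row(chain, resno, "CA", "C", apply_transform(tf, ca)),
    cys_atom_row(chain, resno, "C", "C", apply_transform(tf, cc)),
    cys_atom_row(chain, resno, "O", "O", apply_transform(tf, oo)),
    cys_atom_row(chain, resno, "CB", "C", apply_transform(tf, cb)))
  if (!is.null(chi1)) {
    sg <- place_internal(n, ca, cb, params$bond_length, params$bond_angle,
                         chi1)
    rows <- rbind(rows, cys_atom_row(chain, resno, "SG", "S",
                                     apply_transform(tf, sg)))
  }
  structure_model(rows, entry_id = "SYNC")
}

#' Specification of a synthetic C2-symmetric dimer
#'
#' @param cb_separation CB-CB distance between the two cysteines, Angstrom.
#'   May be `NULL` when `target_quintet` fixes the geometry instead.
#' @param twist extra rotation (degrees) of protomer B about the two-fold
#'   axis, applied after the C2 operation.
#' @param lateral_offset registration shift of protomer B along the
#'   interface (y axis), Angstrom.
#' @param target_quintet optional five angles (chi1, chi2, chi3, chi2p,
#'   chi1p, degrees); when given the partner protomer is built by internal
#'   coordinates so the resulting cystine realises the quintet exactly.
#' @param approach_angle chi1 (degrees) at which the two sulfur cones face
#'   each other most closely in the C2 construction (default -120, the
#'   disulfide-bonded well).
#' @param seed integer, reserved for randomised placements.
#' @return list of class `dimer_spec`.
#' @export
dimer_spec <- function(cb_separation = NULL, twist = 0, lateral_offset = 0,
                       target_quintet = NULL, approach_angle = -120,
                       seed = 1L) {
  if (is.null(cb_separation) && is.null(target_quintet))
    stop("give cb_separation or target_quintet", call. = FALSE)
  if (!is.null(cb_separation) && cb_separation <= 0)
    stop("cb_separation must be positive", call. = FALSE)
  if (!is.null(target_quintet) && length(target_quintet) != 5)
    stop("target_quintet needs five angles", call. = FALSE)
  structure(list(cb_separation = cb_separation, twist = twist,
                 lateral_offset = lateral_offset,
                 target_quintet = target_quintet,
                 approach_angle = approach_angle, seed = as.integer(seed)),
            class = "dimer_spec")
}

# Tilt (degrees) of the cone axis against the inter-protomer direction in
# the C2 construction. At 45 degrees the closest-approach rotamer is unique
# (see closed-form analysis in the methods vignette).
C2_TILT <- 45

# Distance margin between CB-CB separation and the engineered closest S-S
# approach: cb_separation = d_min + 2 (r sin(tilt) + h cos(tilt)).
c2_margin <- function(params = sweep_params(), tilt = C2_TILT) {
  r <- params$bond_length * sin(pi - deg2rad(params$bond_angle))
  h <- params$bond_length * cos(pi - deg2rad(params$bond_angle))
  2 * (r * sin(deg2rad(tilt)) + h * cos(deg2rad(tilt)))
}

#' Dimer spec whose closest virtual S-S approach is a chosen distance
#'
#' Closed-form inverse of the C2 construction: returns a [dimer_spec()]
#' whose unique closest sulfur-sulfur approach, over all rotamer pairs, is
#' `d_min` Angstrom, attained exactly at `(approach_angle, approach_angle)`.
#'
#' @param d_min engineered minimum S-S distance, Angstrom.
#' @param approach_angle chi1 of the closest approach, degrees.
#' @param params a [sweep_params()].
#' @return a [dimer_spec()].
#' @export
dimer_spec_for_min_distance <- function(d_min, approach_angle = -120,
                                        params = sweep_params()) {
  stopifnot(d_min > 0)
  dimer_spec(cb_separation = d_min + c2_margin(params),
             approach_angle = approach_angle)
}

# Rotation mapping orthonormal pair (a1, p1) onto (a2, p2).
frame_rotation <- function(a1, p1, a2, p2) {
  L <- cbind(a1, p1, vcross(a1, p1))
  G <- cbind(a2, p2, vcross(a2, p2))
  G %*% t(L)
}

build_quintet_dimer <- function(spec, params) {
  g <- IDEAL_GEOM
  q <- as.numeric(spec$target_quintet)
  a <- make_ideal_cysteine(chain = "A", resno = 392, chi1 = q[1],
                           params = params)
  at <- a$atoms
  pos <- function(name) as.numeric(at[at$elety == name, c("x", "y", "z")])
  n_a <- pos("N"); ca_a <- pos("CA"); cb_a <- pos("CB"); sg_a <- pos("SG")
  sg_b <- place_internal(ca_a, cb_a, sg_a, g$s_s, g$cb_s_s, q[2])
  cb_b <- place_internal(cb_a, sg_a, sg_b, params$bond_length, g$cb_s_s,
                         q[3])
  ca_b <- place_internal(sg_a, sg_b, cb_b, g$ca_cb, params$bond_angle,
                         q[4])
  n_b <- place_internal(sg_b, cb_b, ca_b, g$n_ca, g$n_ca_cb, q[5])
  c_b <- place_internal(cb_b, n_b, ca_b, g$ca_c, g$n_ca_c, -120)
  o_b <- place_internal(n_b, ca_b, c_b, g$c_o, g$ca_c_o, 0)
  sep <- vnorm(cb_a - cb_b)
  if (!is.null(spec$cb_separation) &&
      abs(sep - spec$cb_separation) > 1e-6)
    stop(sprintf(paste0("target_quintet implies a CB-CB separation of ",
                        "%.6f A, not the requested %.6f A: the quintet ",
                        "fixes the separation"), sep, spec$cb_separation),
         call. = FALSE)
  b_rows <- rbind(cys_atom_row("B", 392, "N", "N", n_b),
                  cys_atom_row("B", 392, "CA", "C", ca_b),
                  cys_atom_row("B", 392, "C", "C", c_b),
                  cys_atom_row("B", 392, "O", "O", o_b),
                  cys_atom_row("B", 392, "CB", "C", cb_b),
                  cys_atom_row("B", 392, "SG", "S", sg_b))
  structure_model(rbind(at, b_rows), entry_id = "SYND")
}

#' Build a C2-symmetric two-cysteine dimer
#'
#' Two cysteine-bearing protomer stubs related by a two-fold rotation about
#' the z axis. The construction tilts each sulfur cone 45 degrees against
#' the inter-protomer direction so the closest virtual S-S approach is
#' unique: it occurs exactly at chi1 = `approach_angle` on both sites, at
#' distance `cb_separation - c2_margin()`. Protomer B is additionally
#' rotated by `twist` about the axis and shifted `lateral_offset` along y.
#' When `target_quintet` is given, the partner protomer is instead built by
#' internal coordinates so the cystine realises the quintet exactly (twist
#' and offset do not apply; the CB-CB separation is then implied by the
#' quintet, and a conflicting requested separation is an error).
#'
#' @param spec a [dimer_spec()].
#' @param params a [sweep_params()].
#' @return a [structure_model()] with chains A and B (Cys-392 each).
#' @export
make_c2_dimer <- function(spec, params = sweep_params()) {
  stopifnot(inherits(spec, "dimer_spec"))
  if (!is.null(spec$target_quintet))
    return(build_quintet_dimer(spec, params))
  d_min <- spec$cb_separation - c2_margin(params)
  if (d_min <= 0)
    stop(sprintf(paste0("cb_separation %.3f A is below the construction ",
                        "margin %.3f A: the sulfur cones would ",
                        "interpenetrate"),
                 spec$cb_separation, c2_margin(params)), call. = FALSE)
  proto <- make_ideal_cysteine(chain = "A", resno = 392, params = params)
  site <- find_cysteines(proto)[[1]]
  circ <- sulfur_circle(site, params)
  s_star <- place_sulfur(site, spec$approach_angle, params)
  tilt <- deg2rad(C2_TILT)
  # target frame: cone axis tilted in the x-z plane, closest-approach
  # radial direction pointing at the two-fold (z) axis
  axis_g <- c(cos(tilt), 0, sin(tilt))
  radial_g <- c(sin(tilt), 0, -cos(tilt))
  R <- frame_rotation(circ$axis, vunit(s_star - circ$center),
                      axis_g, radial_g)
  t <- c(-d_min / 2, 0, 0) - as.numeric(R %*% s_star)
  a_model <- transform_model(proto, rigid_transform(R, t))
  b_atoms <- a_model$atoms
  b_atoms[, c("x", "y", "z")] <- apply_transform(
    rigid_transform(rot_z(180 + spec$twist),
                    c(0, spec$lateral_offset, 0)),
    as.matrix(b_atoms[, c("x", "y", "z")]))
  b_atoms$chain <- "B"
  structure_model(rbind(a_model$atoms, b_atoms), entry_id = "SYND")
}

#' Add a clash-probe pseudoatom covering a chosen sweep arc
#'
#' Places one carbon-radius pseudoatom in the plane of the site's sulfur
#' circle so that [clash_scan()] marks, to within one grid step, exactly
#' the arc `[arc_center - arc_halfwidth, arc_center + arc_halfwidth]` of
#' chi1 angles — emulating a side chain (such as the valine flanking the
#' interchain cysteine) that blocks part of the rotamer circle. The radial
#' probe distance is solved from the overlap criterion in closed form.
#'
#' @param model a [structure_model()] containing the site.
#' @param site a `cysteine_site` of that model.
#' @param arc_center chi1 (degrees) at the arc centre.
#' @param arc_halfwidth half-width in degrees, in `[0, 180)`.
#' @param params a [sweep_params()].
#' @return the model with the probe atom appended (residue `PRB`, two
#'   residues downstream on the site's chain so it is not clash-exempt).
#' @export
add_clash_probe <- function(model, site, arc_center, arc_halfwidth,
                            params = sweep_params()) {
  if (arc_halfwidth < 0 || arc_halfwidth >= 180)
    stop("arc_halfwidth must lie in [0, 180)", call. = FALSE)
  circ <- sulfur_circle(site, params)
  reach <- element_radius("S", params) + element_radius("C", params) -
    params$clash_overlap - 1e-9 # boundary angles clash strictly
  hw <- deg2rad(arc_halfwidth)
  disc <- reach^2 - (circ$radius * sin(hw))^2
  if (disc <= 0)
    stop("arc too wide for the probe reach at this circle radius",
         call. = FALSE)
  rho <- circ$radius * cos(hw) + sqrt(disc)
  s_c <- place_sulfur(site, arc_center, params)
  probe <- circ$center + rho * vunit(s_c - circ$center)
  model$atoms <- rbind(model$atoms,
                       cys_atom_row(site$chain, site$resno + 2L, "CP", "C",
                                    probe, resid = "PRB"))
  model
}

#' Specification of a synthetic dihedral ensemble
#'
#' Wrapped-normal mixtures per angle; wrapped normal (rather than von
#' Mises) so component-recovery formulas stay elementary.
#'
#' @param n sample count.
#' @param components named list (`chi1`, `chi2`, `chi3`) of data.frames
#'   with columns `mean`, `sd` (degrees) and `weight` (summing to 1).
#'   Defaults emulate the canonical rotamer wells: chi1 m/t/p, chi2 at
#'   +/-80, chi3 bimodal near the relaxed +/-90 wells.
#' @param seed integer RNG seed.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n,
                          components = list(
                            chi1 = data.frame(mean = c(-60, 180, 60),
                                              sd = c(10, 10, 10),
                                              weight = c(0.5, 0.3, 0.2)),
                            chi2 = data.frame(mean = c(-80, 80),
                                              sd = c(12, 12),
                                              weight = c(0.5, 0.5)),
                            chi3 = data.frame(mean = c(95, -87),
                                              sd = c(8, 8),
                                              weight = c(0.5, 0.5))),
                          seed = 1L) {
  stopifnot(n >= 0)
  for (nm in names(components)) {
    cmp <- components[[nm]]
    if (abs(sum(cmp$weight) - 1) > 1e-9)
      stop("component weights for ", nm, " must sum to 1", call. = FALSE)
    if (any(cmp$sd <= 0))
      stop("component sd must be positive", call. = FALSE)
  }
  structure(list(n = as.integer(n), components = components,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

sample_wrapped_mixture <- function(n, cmp) {
  if (n == 0) return(numeric())
  k <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
  wrap_angle(stats::rnorm(n, cmp$mean[k], cmp$sd[k]))
}

#' Sample a synthetic survey-record ensemble
#'
#' Seeded, reproducible wrapped-normal mixture draws per angle, emitted in
#' the [collect_cystines()] record layout (synthetic entry ids, resolution
#' 1.5 Angstrom so any survey filter under test passes them). Primed
#' chi1'/chi2' are drawn from the same mixtures independently.
#'
#' @param spec an [ensemble_spec()].
#' @return data.frame of survey records with `spec$n` rows.
#' @export
sample_dihedral_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n
  if (n == 0)
    return(data.frame(entry_id = character(), resolution = numeric(),
                      site_a = character(), site_b = character(),
                      chi1 = numeric(), chi2 = numeric(), chi3 = numeric(),
                      chi2p = numeric(), chi1p = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(entry_id = sprintf("SYN%05d", seq_len(n)), resolution = 1.5,
             site_a = "A:1", site_b = "B:1",
             chi1 = sample_wrapped_mixture(n, spec$components$chi1),
             chi2 = sample_wrapped_mixture(n, spec$components$chi2),
             chi3 = sample_wrapped_mixture(n, spec$components$chi3),
             chi2p = sample_wrapped_mixture(n, spec$components$chi2),
             chi1p = sample_wrapped_mixture(n, spec$components$chi1),
             stringsAsFactors = FALSE)
}

#' Write a model as a fixed-column PDB fixture
#'
#' Fixture-only writer (the package never rewrites real structures): emits
#' HEADER with the entry id, a REMARK 2 resolution record when present,
#' and one fixed-column coordinate record per atom, altlocs included.
#' Round-trips through [read_structure()] to 1e-3 Angstrom (PDB precision).
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param record `"ATOM"` or `"HETATM"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(model, path, record = "ATOM") {
  at <- model$atoms
  lines <- sprintf("HEADER    SYNTHETIC FIXTURE%45s%4s", "",
                   substr(model$entry_id, 1, 4))
  if (!is.na(model$resolution))
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", model$resolution))
  if (nrow(at)) {
    name <- ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety)
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, seq_len(nrow(at)), name, at$altloc, at$resid, at$chain,
      at$resno, at$insert, at$x, at$y, at$z, at$occ, at$b, at$element))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
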