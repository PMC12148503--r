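#' Parameters of the chi1-sweep accessibility scan
#'
#' Bundles the geometric constants of the virtual-sulfur sweep: the CB-S
#' bond length (1.81 Angstrom), the CA-CB-S angle (114.3 degrees), the
#' 1-degree sweep step, the ideal S-S bond length 2.0 +/- 0.1 Angstrom used
#' as the feasibility band, and the steric-clash criterion (van der Waals
#' overlap beyond 0.4 Angstrom against heavy atoms with standard radii).
#'
#' @param bond_length CB-S distance, Angstrom.
#' @param bond_angle CA-CB-S angle, degrees.
#' @param step sweep increment in degrees; must divide 360.
#' @param ss_target ideal S-S bond length, Angstrom.
#' @param ss_tolerance half-width of the permissible S-S band, Angstrom.
#' @param clash_overlap vdW overlap beyond which a contact is a clash,
#'   Angstrom.
#' @param vdw_radii named per-element radius table, Angstrom; elements not
#'   listed fall back to `default_radius`.
#' @param default_radius fallback vdW radius, Angstrom.
#' @return list of class `sweep_params`.
#' @export
sweep_params <- function(bond_length = 1.81, bond_angle = 114.3, step = 1,
                         ss_target = 2.0, ss_tolerance = 0.1,
                         clash_overlap = 0.4,
                         vdw_radii = c(S = 1.80, C = 1.70, N = 1.55, O = 1.52),
                         default_radius = 1.70) {
  stopifnot(bond_length > 0, bond_angle > 0, bond_angle < 180,
            ss_tolerance >= 0)
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("step must be a positive divisor of 360", call. = FALSE)
  structure(list(bond_length = bond_length, bond_angle = bond_angle,
                 step = step, ss_target = ss_target,
                 ss_tolerance = ss_tolerance, clash_overlap = clash_overlap,
                 vdw_radii = vdw_radii, default_radius = default_radius),
            class = "sweep_params")
}

element_radius <- function(el, params) {
  r <- params$vdw_radii[el]
  r[is.na(r)] <- params$default_radius
  unname(r)
}

#' Place a virtual sulfur at a given chi1
#'
#' The unique point at `bond_length` from CB, making `bond_angle` at CB with
#' CA, with torsion N-CA-CB-S equal to `chi1`. Equivalent to the
#' radial/height construction: a height component along the CA-CB unit
#' vector of `bond_length * cos(pi - bond_angle)` plus a radial component of
#' magnitude `bond_length * sin(pi - bond_angle)` rotated by chi1 about the
#' axis.
#'
#' @param site a `cysteine_site`.
#' @param chi1 torsion in degrees.
#' @param params a [sweep_params()].
#' @return length-3 sulfur position, Angstrom.
#' @export
place_sulfur <- function(site, chi1, params = sweep_params()) {
  place_internal(site$n, site$ca, site$cb,
                 bond = params$bond_length, angle = params$bond_angle,
                 tors = chi1)
}

# Geometry of the sulfur cone: circle centre, radius and orthonormal basis.
sulfur_circle <- function(site, params = sweep_params()) {
  u <- vunit(site$cb - site$ca)
  h <- params$bond_length * cos(pi - deg2rad(params$bond_angle))
  r <- params$bond_length * sin(pi - deg2rad(params$bond_angle))
  list(center = site$cb + h * u, axis = u, radius = r, height = h)
}

#' Sweep all chi1 rotamers of a site
#'
#' One virtual-sulfur position per grid angle; the grid spans `(-180, 180]`
#' anchored at `-180 + step` so the canonical rotamer wells lie on grid
#' points. All positions lie on a circle about the CA-CB axis.
#'
#' @param site a `cysteine_site`.
#' @param params a [sweep_params()].
#' @return object of class `sweep_profile`: list with `site`, `params`,
#'   `angles`, `pos` (n x 3 matrix), and empty `clash`/`min_cross` slots
#'   filled by [clash_scan()] / [min_cross_distances()].
#' @export
sweep_positions <- function(site, params = sweep_params()) {
  angles <- seq(-180 + params$step, 180, by = params$step)
  pos <- t(vapply(angles, function(a) place_sulfur(site, a, params),
                  numeric(3)))
  structure(list(site = site, params = params, angles = angles, pos = pos,
                 clash = NULL, clash_atoms = NULL,
                 min_cross = NULL, partner_angle = NULL),
            class = "sweep_profile")
}

# Indices of model atoms exempt from clash testing against this site's
# virtual sulfur: the site's own residue plus backbone N/C/O of its
# immediate sequence neighbours (1-2/1-3/1-4 relationships), plus hydrogens.
clash_exempt <- function(model, site) {
  at <- model$atoms
  own <- at$chain == site$chain & at$resno == site$resno &
    at$insert == site$insert
  nb <- at$chain == site$chain & abs(at$resno - site$resno) == 1 &
    at$elety %in% c("N", "C", "O")
  own | nb | at$element == "H"
}

#' Mark sterically clashing sweep angles
#'
#' An angle clashes when its virtual sulfur overlaps any non-exempt heavy
#' atom by more than `clash_overlap`, with overlap = (r_S + r_other) -
#' distance. Exempt by default: the site's own residue, the backbone N/C/O
#' of its sequence neighbours, and hydrogens.
#'
#' @param profile a [sweep_positions()] profile.
#' @param model the full structure the sulfur must fit into.
#' @param params a [sweep_params()].
#' @return the profile with `clash` (logical per angle) and `clash_atoms`
#'   (list of offending atom labels per angle) filled.
#' @export
clash_scan <- function(profile, model, params = profile$params) {
  at <- model$atoms[!clash_exempt(model, profile$site), , drop = FALSE]
  n <- length(profile$angles)
  if (!nrow(at)) {
    profile$clash <- rep(FALSE, n)
    profile$clash_atoms <- rep(list(character()), n)
    return(profile)
  }
  P <- profile$pos
  Q <- as.matrix(at[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q), 0))
  r_s <- element_radius("S", params)
  reach <- r_s + element_radius(at$element, params) - params$clash_overlap
  hit <- sweep(d, 2, reach, "<")
  profile$clash <- rowSums(hit) > 0
  labs <- paste0(at$chain, ":", at$resno, at$insert, ":", at$elety)
  profile$clash_atoms <- apply(hit, 1, function(h) labs[h],
                               simplify = FALSE)
  profile
}

cross_distance_matrix <- function(profile_a, profile_b) {
  A <- profile_a$pos; B <- profile_b$pos
  sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
}

#' Minimum cross-protomer S-S distance per sweep angle
#'
#' For each angle of site A, the minimum over all angles of site B of the
#' virtual sulfur-sulfur distance, and the partner angle achieving it. By
#' default distances are computed over the full grid (clash filtering is
#' applied later by [feasibility()]); set `use_clash_mask = TRUE` to take
#' minima over clash-free partner angles only.
#'
#' @param profile_a,profile_b `sweep_profile`s on the same grid.
#' @param use_clash_mask exclude clash-marked angles before taking minima.
#' @return `profile_a` with `min_cross` and `partner_angle` filled.
#' @export
min_cross_distances <- function(profile_a, profile_b,
                                use_clash_mask = FALSE) {
  if (!isTRUE(all.equal(profile_a$angles, profile_b$angles)))
    stop("sweep grids differ between the two profiles", call. = FALSE)
  D <- cross_distance_matrix(profile_a, profile_b)
  keep_b <- rep(TRUE, length(profile_b$angles))
  if (use_clash_mask) {
    if (is.null(profile_b$clash))
      stop("use_clash_mask = TRUE but clash mask not computed", call. = FALSE)
    keep_b <- !profile_b$clash
    if (!any(keep_b)) stop("no clash-free partner angles", call. = FALSE)
    D <- D[, keep_b, drop = FALSE]
  }
  j <- apply(D, 1, which.min)
  profile_a$min_cross <- D[cbind(seq_len(nrow(D)), j)]
  profile_a$partner_angle <- profile_b$angles[keep_b][j]
  profile_a
}

#' Decide disulfide feasibility from two sweeps
#'
#' A rotamer pair (thetaA, thetaB) is feasible when both angles are
#' clash-free and the virtual S-S distance does not exceed the maximum
#' permissible bond distance `ss_target + ss_tolerance` (2.1 Angstrom by
#' default). The lower bound `ss_target - ss_tolerance` is optional
#' (`lower_bound = TRUE`) since a closer approach registers physically as a
#' clash.
#'
#' @param profile_a,profile_b clash-scanned `sweep_profile`s on one grid.
#' @param params a [sweep_params()].
#' @param lower_bound also require distance >= `ss_target - ss_tolerance`.
#' @return list of class `feasibility_result`: `feasible_pairs` (data.frame
#'   theta_a, theta_b, distance), `best_pair` (row minimising
#'   |distance - ss_target|, or NULL), `any_feasible`, and `per_angle`
#'   (data.frame angle, clash_a, min_feasible_distance, feasible — the
#'   Fig-style per-angle verdict for site A).
#' @export
feasibility <- function(profile_a, profile_b, params = profile_a$params,
                        lower_bound = FALSE) {
  for (p in list(profile_a, profile_b))
    if (is.null(p$clash))
      stop("run clash_scan() on both profiles first", call. = FALSE)
  D <- cross_distance_matrix(profile_a, profile_b)
  hi <- params$ss_target + params$ss_tolerance
  lo <- if (lower_bound) params$ss_target - params$ss_tolerance else -Inf
  ok <- outer(!profile_a$clash, !profile_b$clash, "&") & D <= hi & D >= lo
  idx <- which(ok, arr.ind = TRUE)
  feasible_pairs <- data.frame(
    theta_a = profile_a$angles[idx[, 1]],
    theta_b = profile_b$angles[idx[, 2]],
    distance = D[idx])
  feasible_pairs <- feasible_pairs[order(feasible_pairs$theta_a,
                                         feasible_pairs$theta_b), ,
                                   drop = FALSE]
  rownames(feasible_pairs) <- NULL
  best_pair <- NULL
  if (nrow(feasible_pairs)) {
    k <- which.min(abs(feasible_pairs$distance - params$ss_target))
    best_pair <- feasible_pairs[k, , drop = FALSE]
  }
  Dok <- D
  Dok[!ok] <- Inf
  mins <- apply(Dok, 1, min)
  per_angle <- data.frame(angle = profile_a$angles, clash_a = profile_a$clash,
                          min_feasible_distance = ifelse(is.finite(mins),
                                                         mins, NA_real_),
                          feasible = is.finite(mins))
  structure(list(feasible_pairs = feasible_pairs, best_pair = best_pair,
                 any_feasible = nrow(feasible_pairs) > 0,
                 per_angle = per_angle),
            class = "feasibility_result")
}

#' Full two-site accessibility scan
#'
#' Convenience wrapper: sweeps both sites, clash-scans them against the
#' model, fills cross distances and returns the feasibility verdict
#' together with both profiles.
#'
#' @param site_a,site_b `cysteine_site`s (typically the interchain cysteine
#'   of each protomer).
#' @param model the full dimer structure.
#' @param params a [sweep_params()].
#' @param lower_bound see [feasibility()].
#' @return list with `profile_a`, `profile_b` and `result`.
#' @export
accessibility_scan <- function(site_a, site_b, model,
                               params = sweep_params(),
                               lower_bound = FALSE) {
  pa <- clash_scan(sweep_positions(site_a, params), model, params)
  pb <- clash_scan(sweep_positions(site_b, params), model, params)
  pa <- min_cross_distances(pa, pb)
  pb <- min_cross_distances(pb, pa)
  list(profile_a = pa, profile_b = pb,
       result = feasibility(pa, pb, params, lower_bound))
}

#' Re-run feasibility under rigid registration shifts of one protomer
#'
#' Applies each transform to the protomer carrying `site_b` (its chain's
#' atoms, including any clash decoys on that chain), repeats the scan, and
#' additionally reports the chi3 achieved at the best pair (computed from
#' the placed sulfurs and the fixed CB positions) plus whether an
#' unstrained geometry (|chi3| within `chi3_window` of 90 degrees) is
#' achievable among the feasible pairs.
#'
#' @param site_a,site_b `cysteine_site`s.
#' @param model full dimer structure.
#' @param shifts non-empty list of [rigid_transform()]s.
#' @param params a [sweep_params()].
#' @param chi3_window half-width (degrees) of the unstrained chi3 band
#'   around +/-90.
#' @return list, one element per shift: `result` (a `feasibility_result`),
#'   `best_chi3`, `unstrained_feasible`.
#' @export
registration_shift_scan <- function(site_a, site_b, model, shifts,
                                    params = sweep_params(),
                                    chi3_window = 30) {
  if (!length(shifts)) stop("empty transform grid", call. = FALSE)
  lapply(shifts, function(tf) {
    m <- transform_model(model, tf, chains = site_b$chain)
    sb <- transform_site(site_b, tf)
    sc <- accessibility_scan(site_a, sb, m, params)
    res <- sc$result
    chi3_of <- function(ta, tb)
      torsion_angle(site_a$cb, place_sulfur(site_a, ta, params),
                    place_sulfur(sb, tb, params), sb$cb)
    best_chi3 <- NA_real_
    unstrained <- FALSE
    if (res$any_feasible) {
      best_chi3 <- chi3_of(res$best_pair$theta_a, res$best_pair$theta_b)
      chi3s <- mapply(chi3_of, res$feasible_pairs$theta_a,
                      res$feasible_pairs$theta_b)
      unstrained <- any(abs(abs(chi3s) - 90) <= chi3_window)
    }
    list(result = res, best_chi3 = best_chi3,
         unstrained_feasible = unstrained)
  })
}

#' Write a per-angle sweep report as TSV
#'
#' Columns: angle, clash, clashing atoms, minimum cross distance and the
#' partner angle achieving it (when computed).
#'
#' @param profile a `sweep_profile`.
#' @param path output file.
#' @export
write_sweep_tsv <- function(profile, path) {
  df <- data.frame(angle = profile$angles,
                   clash = if (is.null(profile$clash)) NA else profile$clash,
                   clash_atoms = if (is.null(profile$clash_atoms)) ""
                   else vapply(profile$clash_atoms, paste, "", collapse = ","),
                   min_cross = if (is.null(profile$min_cross)) NA_real_
                   else profile$min_cross,
                   partner_angle = if (is.null(profile$partner_angle))
                     NA_real_ else profile$partner_angle)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sweep sulfur circles as a pseudoatom PDB file
#'
#' One HETATM sulfur per grid angle (residue name `PSS`), mirroring the
#' pseudoatom circles used to visualise possible sulfur positions.
#'
#' @param profile a `sweep_profile`.
#' @param path output file.
#' @param chain chain id for the pseudoatoms.
#' @export
write_pseudoatoms <- function(profile, path, chain = "Z") {
  n <- nrow(profile$pos)
  atoms <- data.frame(chain = chain, resno = seq_len(n), insert = "",
                      resid = "PSS", elety = "S", element = "S",
                      altloc = "", occ = 1,
                      b = ifelse(is.null(profile$clash), 0,
                                 as.numeric(profile$clash)),
                      x = profile$pos[, 1], y = profile$pos[, 2],
                      z = profile$pos[, 3])
  write_fixture(structure_model(atoms, entry_id = "PSEU"), path,
                record = "HETATM")
}
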