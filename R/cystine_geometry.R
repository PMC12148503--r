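#' Cystine dihedral quintet
#'
#' The five torsions of a disulfide bridge under the standard definitions:
#' chi1 = N-CA-CB-SG, chi2 = CA-CB-SG-SG', chi3 = CB-SG-SG'-CB', and the
#' primed pair on the partner side. The unprimed site is the one sorting
#' first on (chain, residue number), so the quintet is canonical; chi3 is
#' independent of which side is unprimed.
#'
#' @param pair a `cystine_pair` from [detect_disulfides()].
#' @return named numeric `c(chi1, chi2, chi3, chi2p, chi1p)` of class
#'   `dihedral_quintet`, degrees in `(-180, 180]`.
#' @export
cystine_dihedrals <- function(pair) {
  a <- pair$site_a; b <- pair$site_b
  if (is.null(a$sg) || is.null(b$sg))
    stop("incomplete cystine: both sites need a modeled SG", call. = FALSE)
  q <- c(chi1  = torsion_angle(a$n, a$ca, a$cb, a$sg),
         chi2  = torsion_angle(a$ca, a$cb, a$sg, b$sg),
         chi3  = torsion_angle(a$cb, a$sg, b$sg, b$cb),
         chi2p = torsion_angle(b$ca, b$cb, b$sg, a$sg),
         chi1p = torsion_angle(b$n, b$ca, b$cb, b$sg))
  structure(q, class = "dihedral_quintet")
}

#' Sign quintet and chi3 handedness of a cystine
#'
#' Right-handed disulfides have chi3 > 0, left-handed chi3 < 0. Angles of
#' exactly 0 degrees get "+" in the sign quintet by convention but are
#' flagged as boundary cases, and a chi3 of exactly 0 (the syn-periplanar
#' conformation) is assigned no handedness (`NA`) rather than silently
#' acquiring one.
#'
#' @param q a `dihedral_quintet` (or named numeric of five angles).
#' @return list with `signs` (character quintet of "+"/"-"), `handedness`
#'   (`"right"`, `"left"` or `NA`), and `boundary` (logical quintet marking
#'   exact zeros).
#' @export
screw_signs <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 5)
  signs <- ifelse(q < 0, "-", "+")
  boundary <- q == 0
  handedness <- if (q[3] > 0) "right" else if (q[3] < 0) "left" else NA_character_
  list(signs = stats::setNames(signs, c("chi1", "chi2", "chi3", "chi2p", "chi1p")),
       handedness = handedness, boundary = boundary)
}

# Standard atomic masses. Average: IUPAC 2021 conventional weights;
# monoisotopic: principal-isotope masses.
.MASS_AVG  <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
.MASS_MONO <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, S = 31.97207100)

#' Mass shift of protein cysteinylation
#'
#' Covalent attachment of a free cysteine (C3H7NO2S) to a protein thiol via
#' a disulfide releases two hydrogens, so the adduct adds the cysteine mass
#' minus 2 H: about 119.14 Da average (119 Da at integer precision,
#' round-half-away-from-zero) or 119.004 Da monoisotopic. This is the mass
#' increment seen by intact-mass spectrometry of a cysteinylated monomer.
#'
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass shift in daltons.
#' @export
cysteinylation_mass_shift <- function(kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  m <- if (kind == "average") .MASS_AVG else .MASS_MONO
  cys <- 3 * m["C"] + 7 * m["H"] + m["N"] + 2 * m["O"] + m["S"]
  unname(cys - 2 * m["H"])
}

#' Tabulate every cystine of a model
#'
#' Convenience front end: resolves altlocs, finds cysteines, detects
#' disulfides and emits one row per cystine with the dihedral quintet, sign
#' quintet, handedness, torsion energies and Sg-Sg distance — the per-cystine
#' record the survey and reports consume.
#'
#' @param model a [structure_model()].
#' @param max_ss disulfide detection cutoff, Angstrom.
#' @return data.frame, one row per cystine (zero rows if none).
#' @export
cystine_table <- function(model, max_ss = 2.3) {
  det <- detect_disulfides(find_cysteines(select_altloc(model)), max_ss)
  rows <- lapply(det$pairs, function(p) {
    q <- cystine_dihedrals(p)
    s <- screw_signs(q)
    e <- torsion_energies(q)
    data.frame(entry_id = model$entry_id, resolution = model$resolution,
               site_a = p$site_a$key, site_b = p$site_b$key,
               interchain = p$interchain, ss_distance = p$ss_distance,
               chi1 = q[[1]], chi2 = q[[2]], chi3 = q[[3]],
               chi2p = q[[4]], chi1p = q[[5]],
               signs = paste(s$signs, collapse = ""),
               handedness = ifelse(is.na(s$handedness), "boundary",
                                   s$handedness),
               e_total = e$total, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(entry_id = character(), resolution = numeric(),
                      site_a = character(), site_b = character(),
                      interchain = logical(), ss_distance = numeric(),
                      chi1 = numeric(), chi2 = numeric(), chi3 = numeric(),
                      chi2p = numeric(), chi1p = numeric(),
                      signs = character(), handedness = character(),
                      e_total = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
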