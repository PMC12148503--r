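#' Classic AMBER torsion-energy terms for cystine dihedrals
#'
#' The original AMBER force-field cosine terms for the side-chain torsions
#' of a disulfide, in kcal/mol (the unit of that parameter set):
#' \deqn{E_{\chi_1} = 2.0\,(1 + \cos 3\chi_1)}
#' \deqn{E_{\chi_2} = 1.0\,(1 + \cos 3\chi_2)}
#' \deqn{E_{\chi_3} = 3.5\,(1 + \cos 2\chi_3) + 0.6\,(1 + \cos 3\chi_3)}
#' All are non-negative, even and 360-degree periodic. The chi3 term has its
#' unique global maximum (8.2 kcal/mol) at 0 degrees — the syn-periplanar
#' conformation that eclipses the two CB atoms across the S-S bond — and
#' minima of 0.6 near the relaxed +/-90 degree wells.
#'
#' @param chi angle in degrees (any value; wrapped internally by
#'   periodicity).
#' @return energy in kcal/mol.
#' @name torsion_terms
NULL

#' @rdname torsion_terms
#' @export
e_chi1 <- function(chi) 2.0 * (1 + cospi(3 * chi / 180))

#' @rdname torsion_terms
#' @export
e_chi2 <- function(chi) 1.0 * (1 + cospi(3 * chi / 180))

#' @rdname torsion_terms
#' @export
e_chi3 <- function(chi) 3.5 * (1 + cospi(2 * chi / 180)) +
  0.6 * (1 + cospi(3 * chi / 180))

#' Torsion energies of a cystine's dihedral quintet
#'
#' @param q a `dihedral_quintet` (see [cystine_dihedrals()]).
#' @return list with per-dihedral terms `e_chi1`, `e_chi2`, `e_chi3`,
#'   `e_chi2p`, `e_chi1p` and their sum `total`, kcal/mol.
#' @export
torsion_energies <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 5)
  e <- list(e_chi1 = e_chi1(q[1]), e_chi2 = e_chi2(q[2]),
            e_chi3 = e_chi3(q[3]), e_chi2p = e_chi2(q[4]),
            e_chi1p = e_chi1(q[5]))
  e$total <- sum(unlist(e))
  e
}

#' Dense torsion-energy profile over (-180, 180]
#'
#' Grid curve for overlay with survey histograms; the grid is anchored at
#' `-180 + step` so the canonical m/p/t rotamer wells (-60, +60, 180) fall
#' on grid points for integer steps.
#'
#' @param which `"chi1"`, `"chi2"` or `"chi3"`.
#' @param step grid step in degrees; must divide 360.
#' @return data.frame of class `energy_profile` with columns `angle` and
#'   `energy`, plus attributes `argmax`/`argmin` (grid angles attaining the
#'   extrema) and `which`.
#' @export
energy_profile <- function(which = c("chi1", "chi2", "chi3"), step = 1) {
  which <- match.arg(which)
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("step must be a positive divisor of 360", call. = FALSE)
  f <- switch(which, chi1 = e_chi1, chi2 = e_chi2, chi3 = e_chi3)
  angle <- seq(-180 + step, 180, by = step)
  energy <- f(angle)
  out <- data.frame(angle = angle, energy = energy)
  attr(out, "which") <- which
  attr(out, "argmax") <- angle[energy >= max(energy) - 1e-12]
  attr(out, "argmin") <- angle[energy <= min(energy) + 1e-12]
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Write an energy profile as two-column TSV
#'
#' @param profile an [energy_profile()].
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("angle", "energy")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
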