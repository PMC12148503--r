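#' Survey configuration
#'
#' Filters and binning for background cystine dihedral distributions: keep
#' structures at 2.5 Angstrom resolution or better, drop listed entries,
#' and bin angles over \[-180, 180\] at 5-degree width.
#'
#' @param resolution_max resolution cutoff, Angstrom; models with a poorer
#'   or absent stated resolution are dropped.
#' @param exclusion_ids entry ids to drop entirely (e.g. the structures
#'   under study, which must not contribute to their own background).
#' @param bin_width histogram bin width, degrees; must divide 360.
#' @return list of class `survey_config`.
#' @export
survey_config <- function(resolution_max = 2.5, exclusion_ids = character(),
                          bin_width = 5) {
  stopifnot(resolution_max > 0)
  if (bin_width <= 0 || abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("bin_width must be a positive divisor of 360", call. = FALSE)
  structure(list(resolution_max = resolution_max,
                 exclusion_ids = toupper(exclusion_ids),
                 bin_width = bin_width, range = c(-180, 180)),
            class = "survey_config")
}

#' Collect per-cystine survey records from a structure set
#'
#' Applies the survey filters and emits one record per cystine: models are
#' dropped when excluded by id or when their stated resolution misses the
#' cutoff (absent resolution cannot satisfy the cutoff and is dropped);
#' cysteines are used only when their SG has exactly one disulfide partner
#' within the detection threshold with complete N/CA/CB/SG on both sides —
#' free cysteines and sulfurs crowded by several partners ("too many bound
#' atoms") are filtered out. Per-model exclusion counts are reported via
#' `message()`.
#'
#' @param models list of [structure_model()]s.
#' @param cfg a [survey_config()].
#' @param max_ss disulfide detection cutoff, Angstrom.
#' @return data.frame with one row per cystine: entry_id, resolution, site
#'   ids and the dihedral quintet (degrees). Canonical orientation as in
#'   [cystine_dihedrals()].
#' @export
collect_cystines <- function(models, cfg = survey_config(), max_ss = 2.3) {
  recs <- list()
  for (model in models) {
    if (toupper(model$entry_id) %in% cfg$exclusion_ids) {
      message("survey: ", model$entry_id, " excluded by id")
      next
    }
    if (is.na(model$resolution) || model$resolution > cfg$resolution_max) {
      message("survey: ", model$entry_id, " dropped by resolution filter (",
              ifelse(is.na(model$resolution), "absent",
                     sprintf("%.2f A", model$resolution)), ")")
      next
    }
    sites <- find_cysteines(select_altloc(model))
    with_sg <- Filter(function(s) !is.null(s$sg), sites)
    crowded <- character()
    if (length(with_sg) >= 2) {
      sg <- t(vapply(with_sg, function(s) s$sg, numeric(3)))
      d <- as.matrix(stats::dist(sg))
      diag(d) <- Inf
      crowded <- vapply(with_sg, function(s) s$key, "")[
        rowSums(d <= max_ss) > 1]
    }
    det <- withCallingHandlers(
      detect_disulfides(sites, max_ss),
      warning = function(w) invokeRestart("muffleWarning"))
    kept <- Filter(function(p) !(p$site_a$key %in% crowded ||
                                   p$site_b$key %in% crowded), det$pairs)
    n_drop <- length(det$pairs) - length(kept)
    if (n_drop > 0)
      message("survey: ", model$entry_id, ": ", n_drop,
              " cystine(s) dropped (sulfur with multiple partners)")
    for (p in kept) {
      q <- cystine_dihedrals(p)
      recs[[length(recs) + 1L]] <- data.frame(
        entry_id = model$entry_id, resolution = model$resolution,
        site_a = p$site_a$key, site_b = p$site_b$key,
        chi1 = q[[1]], chi2 = q[[2]], chi3 = q[[3]],
        chi2p = q[[4]], chi1p = q[[5]], stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(entry_id = character(), resolution = numeric(),
                      site_a = character(), site_b = character(),
                      chi1 = numeric(), chi2 = numeric(), chi3 = numeric(),
                      chi2p = numeric(), chi1p = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

bin_index <- function(angle, bin_width) {
  i <- floor((wrap_angle(angle) + 180) / bin_width) + 1L
  nb <- as.integer(round(360 / bin_width))
  pmin(i, nb) # +180 closes the last bin
}

#' Bin survey records into a dihedral histogram
#'
#' Half-open bins \[lo, hi) over \[-180, 180\] with +180 assigned to the
#' last bin; counts conserve the record number and `freq` normalises to 1
#' (per-bin probability; divide by `bin_width` for a density).
#'
#' @param records data.frame from [collect_cystines()] or
#'   [sample_dihedral_ensemble()] (any data.frame with the angle column).
#' @param which angle column to bin: `"chi1"`, `"chi2"`, `"chi3"`,
#'   `"chi2p"` or `"chi1p"`; `"chi1"` and `"chi2"` pool the primed column
#'   too when present, since both sides of a cystine contribute to the
#'   background.
#' @param cfg a [survey_config()].
#' @param pool_primed pool chi1/chi1p (chi2/chi2p) when both present.
#' @return list of class `dihedral_histogram` with `edges`, `mids`,
#'   `counts`, `freq`, `n`, `which`, `bin_width`.
#' @export
build_histogram <- function(records, which = c("chi1", "chi2", "chi3",
                                               "chi2p", "chi1p"),
                            cfg = survey_config(), pool_primed = TRUE) {
  which <- match.arg(which)
  if (!nrow(records)) stop("empty survey: no records to bin", call. = FALSE)
  ang <- records[[which]]
  primed <- c(chi1 = "chi1p", chi2 = "chi2p")[which]
  if (pool_primed && !is.na(primed) && primed %in% names(records))
    ang <- c(ang, records[[primed]])
  ang <- ang[!is.na(ang)]
  if (!length(ang)) stop("empty survey: no finite angles", call. = FALSE)
  nb <- as.integer(round(360 / cfg$bin_width))
  counts <- tabulate(bin_index(ang, cfg$bin_width), nbins = nb)
  edges <- seq(-180, 180, by = cfg$bin_width)
  structure(list(edges = edges, mids = edges[-1] - cfg$bin_width / 2,
                 counts = counts, freq = counts / sum(counts),
                 n = length(ang), which = which,
                 bin_width = cfg$bin_width),
            class = "dihedral_histogram")
}

#' Rarity of an observed angle against a background histogram
#'
#' Returns the frequency of the bin containing the angle together with a
#' rarity score: the fraction of background records falling in bins whose
#' frequency is less than or equal to that bin's. A score near 0 marks an
#' extreme outlier (the angle sits where the background has essentially no
#' mass); a score of 1 marks the modal bin.
#'
#' @param angle degrees.
#' @param hist a [build_histogram()] result.
#' @return list with `bin_freq` and `rarity`, both in \[0, 1\].
#' @export
empirical_percentile <- function(angle, hist) {
  stopifnot(inherits(hist, "dihedral_histogram"))
  f <- hist$freq[bin_index(angle, hist$bin_width)]
  list(bin_freq = f, rarity = sum(hist$freq[hist$freq <= f]))
}

#' Write a histogram as TSV (angle bin mid, count, frequency)
#'
#' Column layout matches the energy-profile TSV so the two overlay.
#'
#' @param hist a [build_histogram()] result.
#' @param path output file.
#' @export
write_histogram_tsv <- function(hist, path) {
  utils::write.table(
    data.frame(angle = hist$mids, count = hist$counts, freq = hist$freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
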