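#' Atomic structure model
#'
#' A light uniform container over parsed PDB/mmCIF coordinates: one row per
#' atom with chain, residue, atom-name, altloc, occupancy, B-factor, element
#' and Cartesian position (Angstrom), plus entry-level metadata (entry id,
#' resolution where the header states one, source format).
#'
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, altloc, occ, b, x, y, z.
#' @param entry_id character entry identifier.
#' @param resolution numeric, Angstrom, or `NA` when the header has none.
#' @param source_format `"pdb"` or `"mmcif"`.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, entry_id = "XXXX", resolution = NA_real_,
                            source_format = c("pdb", "mmcif")) {
  source_format <- match.arg(source_format)
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "altloc", "occ", "b", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.na(resolution) && resolution <= 0)
    stop("resolution must be positive when present", call. = FALSE)
  atoms <- as.data.frame(atoms)[, need]
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms,
                 resolution = as.numeric(resolution),
                 source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, resolution %s (%s)\n",
              x$entry_id, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno", "insert")])),
              ifelse(is.na(x$resolution), "n/a",
                     sprintf("%.2f A", x$resolution)),
              x$source_format))
  invisible(x)
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Resolution from raw header text: REMARK 2 (PDB) or _refine.ls_d_res_high.
scrape_resolution <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rl)) {
      tail_part <- sub(".*RESOLUTION\\.?", "", rl[1])
      m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
      if (length(m)) return(as.numeric(m))
    }
  } else {
    rl <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", rl[1]))
      if (length(m)) return(as.numeric(trimws(m)))
    }
  }
  NA_real_
}

scrape_entry_id <- function(path, format) {
  lines <- readLines(path, n = 50, warn = FALSE)
  if (format == "pdb") {
    hd <- grep("^HEADER", lines, value = TRUE)
    if (length(hd) && nchar(hd[1]) >= 66) {
      id <- trimws(substr(hd[1], 63, 66))
      if (nzchar(id)) return(id)
    }
  } else {
    hd <- grep("^data_", lines, value = TRUE)
    if (length(hd)) return(sub("^data_", "", hd[1]))
  }
  toupper(sub("\\.[^.]*$", "", basename(path)))
}

#' Read a PDB or mmCIF file into a `structure_model`
#'
#' Parsing is delegated to bio3d (`read.pdb` / `read.cif`); the first model
#' of multi-model files is used, waters are dropped, and the stated
#' resolution is captured from `REMARK 2` / `_refine.ls_d_res_high` when
#' present. Hydrogens are retained in the table but ignored by downstream
#' clash logic (the X-ray models in scope lack them).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly", call. = FALSE))
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb")
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || !nrow(at))
    stop("failed to parse ", path, ": no coordinate records found",
         call. = FALSE)
  at <- at[!(at$resid %in% WATER_NAMES), , drop = FALSE]
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  if (any(bad)) # fall back on the leading letter of the atom name
    element[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = toupper(trimws(element)),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  structure_model(atoms,
                  entry_id = scrape_entry_id(path, format),
                  resolution = scrape_resolution(path, format),
                  source_format = format)
}

#' Resolve alternate locations to a single conformer per atom
#'
#' @param model a [structure_model()].
#' @param policy `"highest_occupancy"` (default; ties broken by altloc label
#'   order) or `"label"` (keep a named altloc, blank-altloc atoms always
#'   kept).
#' @param label altloc character to keep under `policy = "label"`.
#' @return model with exactly one position per (residue, atom name).
#' @export
select_altloc <- function(model, policy = c("highest_occupancy", "label"),
                          label = "A") {
  policy <- match.arg(policy)
  at <- model$atoms
  if (all(at$altloc == "")) return(model)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- logical(nrow(at))
  for (idx in split(seq_len(nrow(at)), key)) {
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    if (policy == "label") {
      sel <- idx[at$altloc[idx] %in% c("", label)]
      if (!length(sel)) sel <- idx[order(at$altloc[idx])][1]
      keep[sel[1]] <- TRUE
    } else {
      ord <- idx[order(-at$occ[idx], at$altloc[idx])]
      keep[ord[1]] <- TRUE
    }
  }
  model$atoms <- at[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

residue_key <- function(chain, resno, insert) paste0(chain, ":", resno, insert)

#' One cysteine's anchor atoms
#'
#' @keywords internal
cysteine_site <- function(chain, resno, insert, n, ca, cb, sg = NULL,
                          is_free = NA) {
  d <- vnorm(ca - cb)
  if (d < 1.2 || d > 1.9)
    stop(sprintf("CA-CB distance %.2f A outside sanity band [1.2, 1.9] for %s",
                 d, residue_key(chain, resno, insert)), call. = FALSE)
  structure(list(chain = chain, resno = resno, insert = insert,
                 key = residue_key(chain, resno, insert),
                 n = n, ca = ca, cb = cb, sg = sg, is_free = is_free),
            class = "cysteine_site")
}

#' Locate cysteine residues and their anchor atoms
#'
#' One site per CYS residue carrying N, CA and CB (SG attached when
#' modeled); residues missing an anchor atom are excluded with a warning.
#' Altlocs must already be resolved (see [select_altloc()]).
#'
#' @param model a [structure_model()].
#' @return list of `cysteine_site` objects.
#' @export
find_cysteines <- function(model) {
  at <- model$atoms
  cys <- at[at$resid == "CYS", , drop = FALSE]
  if (!nrow(cys)) return(list())
  sites <- list()
  for (idx in split(seq_len(nrow(cys)),
                    paste(cys$chain, cys$resno, cys$insert, sep = "\r"))) {
    r <- cys[idx, , drop = FALSE]
    pos <- function(name) {
      i <- which(r$elety == name)
      if (!length(i)) return(NULL)
      as.numeric(r[i[1], c("x", "y", "z")])
    }
    n <- pos("N"); ca <- pos("CA"); cb <- pos("CB")
    key <- residue_key(r$chain[1], r$resno[1], r$insert[1])
    if (is.null(n) || is.null(ca) || is.null(cb)) {
      warning("cysteine ", key, " missing backbone/CB anchor atoms; excluded",
              call. = FALSE)
      next
    }
    sites[[key]] <- cysteine_site(r$chain[1], r$resno[1], r$insert[1],
                                  n, ca, cb, sg = pos("SG"))
  }
  # stable residue order
  sites[order(vapply(sites, function(s) s$chain, ""),
              vapply(sites, function(s) as.numeric(s$resno), 0))]
}

#' Pair cysteines into disulfides by Sg-Sg distance
#'
#' Greedy assignment by ascending Sg-Sg distance with a 2.3 Angstrom default
#' cutoff (the ideal 2.0 +/- 0.1 Angstrom bond plus refinement slack); each
#' sulfur joins at most one partner and leftover sites are flagged free. A
#' sulfur still within the cutoff of a second partner after assignment
#' raises an ambiguity warning.
#'
#' @param sites list of `cysteine_site` (from [find_cysteines()]).
#' @param max_ss Sg-Sg cutoff, Angstrom.
#' @return list with `pairs` (list of `cystine_pair`) and `sites` (the input
#'   sites with `is_free` filled).
#' @export
detect_disulfides <- function(sites, max_ss = 2.3) {
  has_sg <- vapply(sites, function(s) !is.null(s$sg), logical(1))
  cand <- which(has_sg)
  pairs <- list()
  taken <- rep(FALSE, length(sites))
  if (length(cand) >= 2) {
    combs <- utils::combn(cand, 2)
    d <- apply(combs, 2, function(ij)
      vnorm(sites[[ij[1]]]$sg - sites[[ij[2]]]$sg))
    ord <- order(d)
    n_within <- integer(length(sites))
    for (k in seq_along(ord)) {
      if (d[ord[k]] > max_ss) break
      ij <- combs[, ord[k]]
      n_within[ij] <- n_within[ij] + 1L
      if (taken[ij[1]] || taken[ij[2]]) next
      taken[ij] <- TRUE
      a <- sites[[ij[1]]]; b <- sites[[ij[2]]]
      # canonical ordering: unprimed site sorts first on (chain, resno)
      if (order(c(paste(a$chain, sprintf("%08d", a$resno)),
                  paste(b$chain, sprintf("%08d", b$resno))))[1] == 2) {
        tmp <- a; a <- b; b <- tmp
      }
      pairs[[length(pairs) + 1L]] <- structure(
        list(site_a = a, site_b = b, ss_distance = d[ord[k]],
             interchain = a$chain != b$chain),
        class = "cystine_pair")
    }
    amb <- which(n_within > 1L)
    if (length(amb))
      warning("sulfur(s) within max_ss of multiple partners: ",
              paste(vapply(sites[amb], function(s) s$key, ""),
                    collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sites)) sites[[i]]$is_free <- !taken[i]
  list(pairs = pairs, sites = sites)
}

# "chain:resno:atomname" selector; atom name part supports glob patterns.
resolve_selector <- function(model, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("selector '", sel, "' is not of the form chain:resno:atomname",
         call. = FALSE)
  at <- model$atoms
  ok <- rep(TRUE, nrow(at))
  if (parts[1] != "*") ok <- ok & at$chain == parts[1]
  if (parts[2] != "*") ok <- ok & at$resno == as.integer(parts[2])
  ok <- ok & grepl(utils::glob2rx(parts[3]), at$elety)
  idx <- which(ok)
  if (!length(idx))
    stop("selector '", sel, "' matches no atoms", call. = FALSE)
  idx
}

#' Measure a distance between selected atoms
#'
#' Selectors are `"chain:resno:atomname"` strings; the atom-name field
#' accepts glob patterns (e.g. `"A:351:OE*"` for both carboxylate oxygens).
#' Mode `"single"` requires one atom per side; `"min_over_set"` reports the
#' minimum over the selection product. Distances are reported to 0.01
#' Angstrom.
#'
#' @param model a [structure_model()].
#' @param sel_a,sel_b selector strings.
#' @param mode `"single"` or `"min_over_set"`.
#' @return distance in Angstrom, rounded to 0.01.
#' @export
measure_distance <- function(model, sel_a, sel_b,
                             mode = c("single", "min_over_set")) {
  mode <- match.arg(mode)
  ia <- resolve_selector(model, sel_a)
  ib <- resolve_selector(model, sel_b)
  if (mode == "single" && (length(ia) > 1 || length(ib) > 1))
    stop("mode 'single' needs exactly one atom per selector; got ",
         length(ia), " and ", length(ib),
         " (use mode = 'min_over_set')", call. = FALSE)
  A <- as.matrix(model$atoms[ia, c("x", "y", "z")])
  B <- as.matrix(model$atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  round(sqrt(max(0, min(d2))), 2)
}

# All atom coordinates of one residue's site, as an n x 3 matrix.
site_anchor_matrix <- function(site) {
  rbind(site$n, site$ca, site$cb, if (!is.null(site$sg)) site$sg)
}

#' Apply a rigid transform to a whole model or a chain subset
#'
#' @param model a [structure_model()].
#' @param tf a [rigid_transform()].
#' @param chains optional character vector: transform only these chains.
#' @return transformed model.
#' @export
transform_model <- function(model, tf, chains = NULL) {
  at <- model$atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(at)) else at$chain %in% chains
  xyz <- apply_transform(tf, as.matrix(at[sel, c("x", "y", "z")]))
  at[sel, c("x", "y", "z")] <- xyz
  model$atoms <- at
  model
}

transform_site <- function(site, tf) {
  site$n <- apply_transform(tf, site$n)
  site$ca <- apply_transform(tf, site$ca)
  site$cb <- apply_transform(tf, site$cb)
  if (!is.null(site$sg)) site$sg <- apply_transform(tf, site$sg)
  site
}
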