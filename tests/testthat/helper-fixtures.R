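# Shared fixture builders. Everything is generated in code; no binary data.

vlen <- function(a) sqrt(sum(a * a))

# A dimer whose unique closest virtual S-S approach is `d_min` at
# (theta, theta), with clash probes optionally blocking all but `theta`.
feasible_dimer <- function(d_min = 2.05, theta = -120, block_rest = FALSE,
                           params = sweep_params()) {
  m <- make_c2_dimer(dimer_spec_for_min_distance(d_min, theta, params),
                     params)
  if (block_rest) {
    sites <- find_cysteines(m)
    opp <- wrap_angle(theta + 180)
    m <- add_clash_probe(m, sites[[1]], opp, 179, params)
    m <- add_clash_probe(m, sites[[2]], opp, 179, params)
  }
  m
}

dimer_sites <- function(model) find_cysteines(select_altloc(model))

# Independent naive clash oracle: per-angle loop over all non-exempt atoms.
oracle_clash <- function(profile, model, params = profile$params) {
  exempt <- cystinescan:::clash_exempt(model, profile$site)
  at <- model$atoms[!exempt, , drop = FALSE]
  r_s <- cystinescan:::element_radius("S", params)
  vapply(seq_along(profile$angles), function(i) {
    s <- profile$pos[i, ]
    any(vapply(seq_len(nrow(at)), function(j) {
      d <- vlen(s - as.numeric(at[j, c("x", "y", "z")]))
      (r_s + cystinescan:::element_radius(at$element[j], params)) - d >
        params$clash_overlap
    }, logical(1)))
  }, logical(1))
}

# Independent exhaustive min-distance oracle: double loop over the grids.
oracle_min_cross <- function(profile_a, profile_b) {
  n <- length(profile_a$angles)
  mins <- numeric(n)
  argmin <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(profile_b$pos) - profile_a$pos[i, ])^2))
    mins[i] <- min(d)
    argmin[i] <- profile_b$angles[which.min(d)]
  }
  list(min = mins, argmin = argmin)
}

# Minimal mmCIF text for one residue (used to exercise the mmcif path).
write_min_cif <- function(path, atoms, res_high = 1.9) {
  hdr <- c("data_TCIF", "#",
           sprintf("_refine.ls_d_res_high %.2f", res_high), "#",
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$elety, atoms$resid,
    atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$resno,
    atoms$resid, atoms$chain, atoms$elety)
  writeLines(c(hdr, rows, "#"), path)
  path
}
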