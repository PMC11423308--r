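# shared fixtures, all generated in code

# noiseless crosspeak record lying exactly on the universal curve
noiseless_record <- function(d, times = c(6, 8, 16, 24) * 71.4e-6,
                             A = 100, noise_sigma = 1, label = "X1CA-CB",
                             site = "1.CA-N") {
  crosspeak_record(label = label, times = times,
                   S = A * (1 - redor_universal(d * times)),
                   S0 = rep(A, length(times)),
                   noise_sigma = noise_sigma, site = site)
}

# noisy replicate of a site, additive Gaussian spectral noise
noisy_record <- function(d, snr = 10, times = c(6, 8, 16, 24) * 71.4e-6,
                         A = 100, label = "X1CA-CB", site = "1.CA-N",
                         ambiguity_group = NA_character_) {
  sg <- A / snr
  crosspeak_record(label = label, times = times,
                   S = A * (1 - redor_universal(d * times)) +
                     rnorm(length(times), 0, sg),
                   S0 = A + rnorm(length(times), 0, sg),
                   noise_sigma = sg, site = site,
                   ambiguity_group = ambiguity_group)
}

# minimal NMR-STAR 3.x file with an atom chemical-shift loop
write_star_fixture <- function(rows, path = tempfile(fileext = ".str")) {
  hdr <- c("data_test", "", "save_assigned_chemical_shifts",
           "   _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
           "", "   loop_",
           "      _Atom_chem_shift.ID",
           "      _Atom_chem_shift.Comp_index_ID",
           "      _Atom_chem_shift.Comp_ID",
           "      _Atom_chem_shift.Atom_ID",
           "      _Atom_chem_shift.Atom_type",
           "      _Atom_chem_shift.Val",
           "")
  body <- sprintf("      %d %d %s %s %s %.3f", seq_len(nrow(rows)),
                  rows$residue, rows$residue_type, rows$atom,
                  rows$atom_type, rows$shift)
  writeLines(c(hdr, body, "   stop_", "save_"), path)
  path
}

star_row <- function(residue, residue_type, atom, shift,
                     atom_type = substr(atom, 1, 1)) {
  data.frame(residue = residue, residue_type = residue_type, atom = atom,
             atom_type = atom_type, shift = shift)
}

# Ala + Gly assignment fixture: 2 + 1 bonded CC pairs
ala_gly_star <- function() {
  write_star_fixture(rbind(
    star_row(1, "ALA", "CA", 52.0),
    star_row(1, "ALA", "CB", 19.0),
    star_row(1, "ALA", "C", 178.0),
    star_row(1, "ALA", "N", 120.0),
    star_row(2, "GLY", "CA", 45.2),
    star_row(2, "GLY", "C", 174.1)))
}
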