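# Shared fixtures, all generated in code.

# A one-carbon PDB file for the reader tests
minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.500   2.250  -3.125  1.00 20.00           C",
    "END"
  ), path)
  path
}

# Small sample with two phantom particles at explicit positions
two_particle_sample <- function() {
  geom <- plane_geometry(400, 400, 200)
  model <- make_phantom_particle(7, 200, 20)
  place_particles(new_sample(geom), model, positions = rbind(c(-60, 0, 0), c(60, 0, 0)),
                  orientations = "identity", seed = 1)
}

# Weak-phase single-atom sample in a thin slab (for optics checks)
thin_atom_sample <- function() {
  geom <- plane_geometry(600, 400, 8)
  atom <- cryotwin:::new_atomic_model("C", 0, 0, 0)
  place_particles(new_sample(geom), atom, count = 1, orientations = "identity")
}

# A two-atom mmCIF file with the canonical RCSB atom_site columns
minimal_cif <- function(path = tempfile(fileext = ".cif")) {
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_entity_id",
            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
            "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
            "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  writeLines(c(
    "data_fixture", "loop_", paste0("_atom_site.", cols),
    "ATOM 1 C CA . ALA A 1 1 ? 1.500 2.250 -3.125 1.00 20.00 ? 1 ALA A CA 1",
    "ATOM 2 N N  . ALA A 1 1 ? 2.500 3.250 -1.125 0.50 20.00 ? 1 ALA A N 1",
    "#"
  ), path)
  path
}

table1_beam <- function() default_config()$beam
table1_lens <- function() default_config()$lens
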