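# Canonical RING finger type table.
#
# Eight zinc-ligand slots per type; slot identity at positions 4 and 5 defines
# the type (H2 = H,H; HC = H,C; v = C,H; C2 = C,C; D = H,D; S/T = H,S-or-T;
# G = H,G); all other slots are cysteine. Boundary slots (1, 2, 7, 8) tolerate
# H or D with a deviation flag, admitting the family-level ligand
# substitutions seen in surveyed repertoires (e.g. an eighth-ligand C-to-D or
# C-to-H in single families).
#
# Seven spacer ranges (residues between consecutive ligands):
#   after 1: 2;  after 2: 9-39;  after 3: 1-3;  after 4: type-specific
#   (2-3 for H2/HC/D/S-T, 4-5 for C2, 7 for v);  after 5: 2;  after 6: 4-48;
#   after 7: 2.
# `ext` is the number of extra residues tolerated with a deviation flag:
# +1 after ligand 4 and +2 after ligand 7, matching the only length
# deviations observed at family level; 0 elsewhere.
version: ringcat-default-1.0
types:
  RING-H2:
    priority: 1
    slot4: [H]
    slot5: [H]
    spacer4: {min: 2, max: 3}
  RING-HC:
    priority: 2
    slot4: [H]
    slot5: [C]
    spacer4: {min: 2, max: 3}
  RING-v:
    priority: 3
    slot4: [C]
    slot5: [H]
    spacer4: {min: 7, max: 7}
  RING-C2:
    priority: 4
    slot4: [C]
    slot5: [C]
    spacer4: {min: 4, max: 5}
  RING-D:
    priority: 5
    slot4: [H]
    slot5: [D]
    spacer4: {min: 2, max: 3}
  RING-S/T:
    priority: 6
    slot4: [H]
    slot5: [S, T]
    spacer4: {min: 2, max: 3}
  RING-G:
    priority: 7
    slot4: [H]
    slot5: [G]
    spacer4: {min: 2, max: 3}
defaults:
  boundary_tolerated: [H, D]
  spacers:
    - {min: 2, max: 2, ext: 0}
    - {min: 9, max: 39, ext: 0}
    - {min: 1, max: 3, ext: 0}
    - {min: 2, max: 3, ext: 1}   # overridden per type by spacer4
    - {min: 2, max: 2, ext: 0}
    - {min: 4, max: 48, ext: 0}
    - {min: 2, max: 2, ext: 2}
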