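# Selected heavy atoms per residue type, in topological order:
# backbone N, CA, CB, then side chain outward (branch points and terminal
# heteroatoms; intermediate ring carbons dropped), then backbone C, O.
# Atom counts are pinned by the reduction rule: ALA 5 (10 angles),
# SER 6 (20), TYR 7 (35), ILE/MET 8 (56), GLN 9 (84), ARG 10 (120).
# Edit and pass via `selection_table(path)` to substitute your own table.
# Atom names are quoted ("N" alone would parse as a YAML boolean).
ALA: ["N", "CA", "CB", "C", "O"]
ARG: ["N", "CA", "CB", "CG", "CD", "NE", "NH1", "NH2", "C", "O"]  # CZ dropped to keep 10 atoms
ASN: ["N", "CA", "CB", "CG", "OD1", "ND2", "C", "O"]
ASP: ["N", "CA", "CB", "CG", "OD1", "OD2", "C", "O"]
CYS: ["N", "CA", "CB", "SG", "C", "O"]
GLN: ["N", "CA", "CB", "CG", "CD", "OE1", "NE2", "C", "O"]
GLU: ["N", "CA", "CB", "CG", "CD", "OE1", "OE2", "C", "O"]
GLY: ["N", "CA", "C", "O"]                        # no CB: 4 atoms, 4 angles
HIS: ["N", "CA", "CB", "CG", "ND1", "NE2", "C", "O"]  # ring CE1/CD2 dropped
ILE: ["N", "CA", "CB", "CG1", "CG2", "CD1", "C", "O"]
LEU: ["N", "CA", "CB", "CG", "CD1", "CD2", "C", "O"]
LYS: ["N", "CA", "CB", "CG", "CD", "CE", "NZ", "C", "O"]
MET: ["N", "CA", "CB", "CG", "SD", "CE", "C", "O"]
PHE: ["N", "CA", "CB", "CG", "CZ", "C", "O"]      # ring CD1/CE1/CE2/CD2 dropped
PRO: ["N", "CA", "CB", "CG", "CD", "C", "O"]      # ring retained
SER: ["N", "CA", "CB", "OG", "C", "O"]
THR: ["N", "CA", "CB", "OG1", "CG2", "C", "O"]
TRP: ["N", "CA", "CB", "CG", "NE1", "CH2", "C", "O"]  # ring interior dropped
TYR: ["N", "CA", "CB", "CG", "OH", "C", "O"]      # ring CD1/CE1/CZ/CE2/CD2 dropped
VAL: ["N", "CA", "CB", "CG1", "CG2", "C", "O"]
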