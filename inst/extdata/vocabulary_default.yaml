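# Default base substructure set Z (49 patterns in three categories).
#
# This is the vocabulary the package ships with; any vocabulary with the same
# fields can be loaded in its place.  Atom-count patterns binarize an atom
# class count by "count >= threshold"; substructure and property patterns are
# SMARTS presence tests evaluated on the monomer with its two attachment
# dummies in place (property-pattern linkers therefore exclude dummy atoms,
# [!#0;!#1]).  Complements z* are derived automatically and never listed.
patterns:
  # -- number of atoms (9 classes) -------------------------------------------
  - id: n_Cl
    category: atom_count
    atom_class: "[Cl]"
    threshold: 1
    description: at least one chlorine
  - id: n_F
    category: atom_count
    atom_class: "[F]"
    threshold: 1
    description: at least one fluorine
  - id: n_N
    category: atom_count
    atom_class: "[N]"
    threshold: 2
    description: two or more aliphatic nitrogens (one is the backbone amine)
  - id: n_O
    category: atom_count
    atom_class: "[O]"
    threshold: 2
    description: two or more oxygens (one is the backbone carbonyl)
  - id: n_C
    category: atom_count
    atom_class: "[C]"
    threshold: 4
    description: four or more aliphatic carbons
  - id: n_Car
    category: atom_count
    atom_class: "[c]"
    threshold: 6
    description: six or more aromatic carbons
  - id: n_S
    category: atom_count
    atom_class: "[S]"
    threshold: 1
    description: at least one sulfur
  - id: n_Nar
    category: atom_count
    atom_class: "[n]"
    threshold: 1
    description: at least one aromatic-ring nitrogen
  - id: n_other
    category: atom_count
    atom_class: "[!#1;!#0;!#6;!#7;!#8;!#16;!#9;!#17]"
    threshold: 1
    description: at least one atom outside C/N/O/S/F/Cl
  # -- substructures (28) ----------------------------------------------------
  - id: s_hydroxyl
    category: substructure
    smarts: "[OX2H]"
    description: hydroxyl group
  - id: s_phenol
    category: substructure
    smarts: "c[OX2H]"
    description: aromatic hydroxyl
  - id: s_carboxyl
    category: substructure
    smarts: "[CX3](=O)[OX2H]"
    description: carboxylic acid (side chain; backbone acid is capped away)
  - id: s_prim_amide
    category: substructure
    smarts: "[CX3](=O)[NX3;H2]"
    description: primary carboxamide
  - id: s_prim_amine
    category: substructure
    smarts: "[NX3;H2;!$([NX3][CX3]=[OX1])]"
    description: primary amine (non-amide)
  - id: s_guanidinium
    category: substructure
    smarts: "[NX3][CX3](=[NX2])[NX3]"
    description: guanidine group
  - id: s_imidazole
    category: substructure
    smarts: "c1c[nH]cn1"
    description: imidazole ring
  - id: s_indole
    category: substructure
    smarts: "c1cc2ccccc2[nH]1"
    description: indole ring system
  - id: s_arom6
    category: substructure
    smarts: "a1aaaaa1"
    description: six-membered aromatic ring
  - id: s_arom5
    category: substructure
    smarts: "a1aaaa1"
    description: five-membered aromatic ring
  - id: s_fused_arom
    category: substructure
    smarts: "[aR2]"
    description: aromatic atom shared by two rings (fused aromatic bicycle)
  - id: s_thiol
    category: substructure
    smarts: "[SX2H]"
    description: thiol
  - id: s_thioether
    category: substructure
    smarts: "[SX2]([#6])[#6]"
    description: thioether
  - id: s_methyl
    category: substructure
    smarts: "[CH3]"
    description: methyl group
  - id: s_gem_dimethyl
    category: substructure
    smarts: "[CH]([CH3])[CH3]"
    description: isopropyl-like branch point
  - id: s_ch2x2
    category: substructure
    smarts: "[CH2][CH2]"
    description: two consecutive methylenes
  - id: s_ch2x3
    category: substructure
    smarts: "[CH2][CH2][CH2]"
    description: three consecutive methylenes
  - id: s_ch2x4
    category: substructure
    smarts: "[CH2][CH2][CH2][CH2]"
    description: four consecutive methylenes
  - id: s_ring_aliph
    category: substructure
    smarts: "[C;R]"
    description: aliphatic ring atom
  - id: s_halogen
    category: substructure
    smarts: "[F,Cl,Br,I]"
    description: any halogen
  - id: s_arom_n_basic
    category: substructure
    smarts: "[nX2]"
    description: pyridine-type aromatic nitrogen
  - id: s_arom_nh
    category: substructure
    smarts: "[nH]"
    description: pyrrole-type aromatic NH
  - id: s_hydroxy_alkyl
    category: substructure
    smarts: "[CX4][OX2H]"
    description: aliphatic alcohol
  - id: s_ether
    category: substructure
    smarts: "[OX2]([CX4])[CX4]"
    description: dialkyl ether
  - id: s_nitrile
    category: substructure
    smarts: "[NX1]#[CX2]"
    description: nitrile
  - id: s_cf3
    category: substructure
    smarts: "[CX4]([F])([F])[F]"
    description: trifluoromethyl
  - id: s_aryl_halide
    category: substructure
    smarts: "c[F,Cl]"
    description: halogen on an aromatic ring
  - id: s_aryl_alkyl
    category: substructure
    smarts: "c[CX4]"
    description: alkyl substituent on an aromatic ring
  # -- properties (12 relational patterns) -----------------------------------
  - id: p_ch2_any_acc
    category: property
    smarts: "[CH2][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: methylene and an H-bond acceptor connected via any atom
  - id: p_ch2_any_don
    category: property
    smarts: "[CH2][!#0;!#1][$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])]"
    description: methylene and an H-bond donor connected via any atom
  - id: p_acc_any_acc
    category: property
    smarts: "[$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: two H-bond acceptors connected via any atom
  - id: p_don_any_don
    category: property
    smarts: "[$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])][!#0;!#1][$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])]"
    description: two H-bond donors connected via any atom
  - id: p_don_adj_acc
    category: property
    smarts: "[$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])]~[$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: H-bond donor directly bonded to an H-bond acceptor
  - id: p_arom_any_acc
    category: property
    smarts: "[a][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: aromatic atom and an H-bond acceptor connected via any atom
  - id: p_arom_any2_don
    category: property
    smarts: "[a][!#0;!#1][!#0;!#1][$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])]"
    description: aromatic atom and an H-bond donor two atoms apart
  - id: p_me_any2_acc
    category: property
    smarts: "[CH3][!#0;!#1][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: methyl and an H-bond acceptor two atoms apart
  - id: p_ch2_het_ch2
    category: property
    smarts: "[CH2][#7,#8,#16][CH2]"
    description: heteroatom flanked by two methylenes
  - id: p_arom_ch2ch2
    category: property
    smarts: "[a][CH2][CH2]"
    description: aromatic ring carrying an ethylene chain
  - id: p_acc_any2_acc
    category: property
    smarts: "[$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])][!#0;!#1][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: two H-bond acceptors three bonds apart
  - id: p_don_any2_acc
    category: property
    smarts: "[$([NX3;H1,H2]),$([OX2H]),$([nH]),$([SX2H])][!#0;!#1][!#0;!#1][$([OX1]),$([OX2H]),$([NX3;H2]),$([nX2])]"
    description: H-bond donor and acceptor three bonds apart
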