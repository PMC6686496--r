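# dfirescore type map, format version 1
#
# Protein side: one line per residue-specific heavy-atom type,
#   RES ATOM MOL2TYPE
# covering every heavy atom of the 20 standard amino acids (167 lines).
# Ligand side: fallbacks for SYBYL types that are not one of the 11
# canonical targets,
#   SYBYL MOL2TYPE
# The 11 canonical targets are exactly the image of the protein map:
#   C.3 C.2 C.ar N.3 N.2 N.ar N.am O.3 O.2 O.co2 S.3
# Edit and reload with read_type_map(); the map is validated on load.
#
# --- protein ---
ALA N N.am
ALA CA C.3
ALA C C.2
ALA O O.2
ALA CB C.3
ARG N N.am
ARG CA C.3
ARG C C.2
ARG O O.2
ARG CB C.3
ARG CG C.3
ARG CD C.3
ARG NE N.2
ARG CZ C.2
ARG NH1 N.2
ARG NH2 N.2
ASN N N.am
ASN CA C.3
ASN C C.2
ASN O O.2
ASN CB C.3
ASN CG C.2
ASN OD1 O.2
ASN ND2 N.am
ASP N N.am
ASP CA C.3
ASP C C.2
ASP O O.2
ASP CB C.3
ASP CG C.2
ASP OD1 O.co2
ASP OD2 O.co2
CYS N N.am
CYS CA C.3
CYS C C.2
CYS O O.2
CYS CB C.3
CYS SG S.3
GLN N N.am
GLN CA C.3
GLN C C.2
GLN O O.2
GLN CB C.3
GLN CG C.3
GLN CD C.2
GLN OE1 O.2
GLN NE2 N.am
GLU N N.am
GLU CA C.3
GLU C C.2
GLU O O.2
GLU CB C.3
GLU CG C.3
GLU CD C.2
GLU OE1 O.co2
GLU OE2 O.co2
GLY N N.am
GLY CA C.3
GLY C C.2
GLY O O.2
HIS N N.am
HIS CA C.3
HIS C C.2
HIS O O.2
HIS CB C.3
HIS CG C.ar
HIS ND1 N.ar
HIS CD2 C.ar
HIS CE1 C.ar
HIS NE2 N.ar
ILE N N.am
ILE CA C.3
ILE C C.2
ILE O O.2
ILE CB C.3
ILE CG1 C.3
ILE CG2 C.3
ILE CD1 C.3
LEU N N.am
LEU CA C.3
LEU C C.2
LEU O O.2
LEU CB C.3
LEU CG C.3
LEU CD1 C.3
LEU CD2 C.3
LYS N N.am
LYS CA C.3
LYS C C.2
LYS O O.2
LYS CB C.3
LYS CG C.3
LYS CD C.3
LYS CE C.3
LYS NZ N.3
MET N N.am
MET CA C.3
MET C C.2
MET O O.2
MET CB C.3
MET CG C.3
MET SD S.3
MET CE C.3
PHE N N.am
PHE CA C.3
PHE C C.2
PHE O O.2
PHE CB C.3
PHE CG C.ar
PHE CD1 C.ar
PHE CD2 C.ar
PHE CE1 C.ar
PHE CE2 C.ar
PHE CZ C.ar
PRO N N.am
PRO CA C.3
PRO C C.2
PRO O O.2
PRO CB C.3
PRO CG C.3
PRO CD C.3
SER N N.am
SER CA C.3
SER C C.2
SER O O.2
SER CB C.3
SER OG O.3
THR N N.am
THR CA C.3
THR C C.2
THR O O.2
THR CB C.3
THR OG1 O.3
THR CG2 C.3
TRP N N.am
TRP CA C.3
TRP C C.2
TRP O O.2
TRP CB C.3
TRP CG C.ar
TRP CD1 C.ar
TRP CD2 C.ar
TRP NE1 N.ar
TRP CE2 C.ar
TRP CE3 C.ar
TRP CZ2 C.ar
TRP CZ3 C.ar
TRP CH2 C.ar
TYR N N.am
TYR CA C.3
TYR C C.2
TYR O O.2
TYR CB C.3
TYR CG C.ar
TYR CD1 C.ar
TYR CD2 C.ar
TYR CE1 C.ar
TYR CE2 C.ar
TYR CZ C.ar
TYR OH O.3
VAL N N.am
VAL CA C.3
VAL C C.2
VAL O O.2
VAL CB C.3
VAL CG1 C.3
VAL CG2 C.3
# --- ligand fallbacks ---
# phosphorus treated like the sulfate/thiol sulfur bucket
P.3 S.3
# halogens
F O.3
Cl S.3
Br S.3
I S.3
# carbon hybridisations outside the canonical 11
C.1 C.2
C.cat C.2
# nitrogen hybridisations outside the canonical 11
N.1 N.2
N.4 N.3
N.pl3 N.2
# water-model oxygens
O.spc O.3
O.t3p O.3
# sulfur variants
S.2 S.3
S.O S.3
S.O2 S.3
S.o S.3
S.o2 S.3
# metal cations, treated as the small-cation (protonated amine) bucket
Li N.3
Na N.3
K N.3
Mg N.3
Ca N.3
Mn N.3
Fe N.3
Co.oh N.3
Cu N.3
Zn N.3
Se S.3
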