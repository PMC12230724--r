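# Molar extinction coefficients at 205 nm (M^-1 cm^-1) for the additive
# scheme of Anthis & Clore (2013) Protein Sci 22:851.
# epsilon(protein) = sum(residue) + (L-1)*peptide_bond
#                    + n_disulfides*disulfide_bond
# The source gives 690 per free cysteine and 820 per cystine bridge, so
# the net disulfide term is 820 - 2*690 = -560.
term,epsilon
A,0
R,1350
N,400
D,0
C,690
E,0
Q,400
G,0
H,5200
I,0
L,0
K,0
M,1830
F,8600
P,0
S,0
T,0
W,20400
Y,6080
V,0
peptide_bond,2780
disulfide_bond,-560
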