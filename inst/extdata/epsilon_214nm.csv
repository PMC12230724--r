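# Molar extinction coefficients at 214 nm (M^-1 cm^-1) for the additive
# peptide scheme of Kuipers & Gruppen (2007) J Agric Food Chem 55:5445.
# epsilon(protein) = sum(residue) + (L-1)*peptide_bond
#                    + n_disulfides*disulfide_bond
# disulfide_bond is the net change per bridge relative to two free
# cysteines (not tabulated at 214 nm; set to 0).
term,epsilon
A,32
R,102
N,136
D,58
C,225
E,78
Q,142
G,21
H,5125
I,45
L,45
K,41
M,980
F,5200
P,2675
S,34
T,41
W,29050
Y,5375
V,43
peptide_bond,923
disulfide_bond,0
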