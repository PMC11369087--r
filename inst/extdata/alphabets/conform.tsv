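# Conformational-similarity reduced alphabet: 7 groups following the
# Pal & Chakrabarti side-chain/main-chain conformational similarity
# scheme (phi/psi shift behaviour). Glycine, proline, cysteine and
# serine keep singleton groups because of their distinctive backbone
# conformational preferences.
# amino_acid	group_label
A	C_1
E	C_1
H	C_1
K	C_1
L	C_1
M	C_1
Q	C_1
R	C_1
C	C_2
D	C_3
N	C_3
F	C_4
I	C_4
T	C_4
V	C_4
W	C_4
Y	C_4
G	C_5
P	C_6
S	C_7
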