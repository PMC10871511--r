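# Free (neutral) proteinogenic amino acids.
# Columns: one-letter code | name | side-chain class | C,H,N,O,S of the free molecule
# The side-chain composition is derived as free molecule minus C2H4NO2.
A | alanine       | aliphatic | 3,7,1,2,0
R | arginine      | basic     | 6,14,4,2,0
N | asparagine    | amide     | 4,8,2,3,0
D | aspartate     | acidic    | 4,7,1,4,0
C | cysteine      | thiol     | 3,7,1,2,1
E | glutamate     | acidic    | 5,9,1,4,0
Q | glutamine     | amide     | 5,10,2,3,0
G | glycine       | none      | 2,5,1,2,0
H | histidine     | aromatic  | 6,9,3,2,0
I | isoleucine    | aliphatic | 6,13,1,2,0
L | leucine       | aliphatic | 6,13,1,2,0
K | lysine        | basic     | 6,14,2,2,0
M | methionine    | aliphatic | 5,11,1,2,1
F | phenylalanine | aromatic  | 9,11,1,2,0
P | proline       | aliphatic | 5,9,1,2,0
S | serine        | alcohol   | 3,7,1,3,0
T | threonine     | alcohol   | 4,9,1,3,0
W | tryptophan    | aromatic  | 11,12,2,2,0
Y | tyrosine      | aromatic  | 9,11,1,3,0
V | valine        | aliphatic | 5,11,1,2,0
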