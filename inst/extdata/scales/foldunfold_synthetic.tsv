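# FoldUnfold-style contact-capacity scale (SYNTHETIC STAND-IN).
# The published scale gives the expected number of close residue contacts a
# residue forms in a globular state (Garbuzynskiy, Lobanov & Galzitskaya).
# The verbatim published values were not available when this file was built;
# these values are a synthetic reconstruction that preserves the published
# ranking (bulky hydrophobics form many contacts; P/G/E/K few). After the
# per-scale standardization applied before PAAC, only relative spacing enters
# the feature computation. Replace with the primary-source table for
# publication-grade runs.
residue	value
A	23.3
C	26.3
D	20.6
E	20.1
F	26.7
G	21.2
H	23.0
I	27.0
K	20.0
L	26.5
M	25.4
N	21.3
P	19.5
Q	21.0
R	21.5
S	21.0
T	22.0
V	26.2
W	25.0
Y	24.3
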