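# DisProt composition-bias scale (SYNTHETIC STAND-IN).
# The published scale ranks residues by the statistical difference between
# their frequencies in experimentally characterized disordered regions and in
# ordered proteins (positive = enriched in disorder). The verbatim published
# values were not available when this file was built; these values are a
# synthetic reconstruction preserving the widely reported ranking
# (order-promoting: W C F I Y V L N M; disorder-promoting: K E P S Q G R A).
# After per-scale standardization only relative spacing enters PAAC.
# Replace with the primary-source table for publication-grade runs.
residue	value
A	0.15
C	-0.80
D	0.10
E	0.70
F	-0.70
G	0.30
H	-0.15
I	-0.60
K	0.60
L	-0.35
M	-0.30
N	-0.10
P	0.55
Q	0.35
R	0.20
S	0.40
T	-0.05
V	-0.40
W	-0.90
Y	-0.50
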