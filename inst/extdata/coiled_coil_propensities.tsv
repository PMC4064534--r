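# Heptad-position propensities for the sliding-window coiled-coil score.
# Columns a-g are the seven heptad register positions; values > 1 mark
# residues enriched at that position in coiled-coil segments.  This is the
# package's own calibrated propensity set in the spirit of the classical
# heptad-repeat method; edit freely, the file is re-read at run time.
residue	a	b	c	d	e	f	g
L	3.20	0.92	0.90	3.00	0.88	0.85	0.90
I	2.60	0.80	0.78	1.90	0.75	0.72	0.78
V	1.80	0.75	0.72	1.30	0.70	0.68	0.72
M	2.20	0.90	0.88	1.60	0.85	0.82	0.85
A	1.60	1.10	1.05	1.40	1.00	0.95	1.00
F	1.20	0.70	0.68	1.00	0.65	0.62	0.68
Y	0.90	0.80	0.78	0.80	0.75	0.78	0.75
W	0.70	0.60	0.58	0.60	0.55	0.55	0.58
E	0.80	1.40	1.35	0.70	1.80	1.30	1.70
Q	0.90	1.30	1.25	0.80	1.50	1.20	1.40
K	0.75	1.30	1.25	0.70	1.60	1.25	1.55
R	0.80	1.25	1.20	0.75	1.50	1.20	1.45
N	0.70	1.10	1.05	0.65	1.00	1.05	1.00
D	0.60	1.10	1.05	0.55	1.00	1.10	1.00
S	0.70	1.00	0.98	0.65	0.95	1.00	0.95
T	0.75	0.95	0.92	0.70	0.90	0.95	0.90
H	0.70	0.95	0.92	0.65	0.90	0.90	0.90
C	0.80	0.70	0.68	0.75	0.65	0.65	0.68
G	0.30	0.60	0.58	0.28	0.55	0.60	0.55
P	0.05	0.10	0.10	0.05	0.10	0.12	0.10
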