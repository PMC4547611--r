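# pKa table "bjellqvist": values from Bjellqvist et al., Electrophoresis 1993,
# as used by the ExPASy Compute pI tool lineage (no neighbour corrections).
# group	pka	kind
NTERM	7.50	basic
CTERM	3.55	acidic
D	4.05	acidic
E	4.45	acidic
C	9.00	acidic
Y	10.00	acidic
H	5.98	basic
K	10.00	basic
R	12.00	basic
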