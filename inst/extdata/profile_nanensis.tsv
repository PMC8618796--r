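# id: W. nanensis SDBR-CMU-S2-17
# Fully resolved outcomes from the species description, restricted to the
# 22 characters of the genus matrix.
character	state
Ga	+
Sor	-
DXy	-
LAr	-
DAr	-
Rh	-
Su	-
Cel	+
Mlb	-
Raf	-
St	-
Rbl	-
DGlu	-
Man	+
Glt	-
2ket	-
Cit	+
NO3	w
vitfree	w
g37C	-
AscMEA	-
Hyph	-
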