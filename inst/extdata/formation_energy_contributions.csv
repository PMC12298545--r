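# Group-contribution formation-stability surrogate (kJ/mol).
# Positive = stabilizing, so well-formed organic structures score >= 0
# and the default stability threshold of 0 kJ/mol is satisfiable.
# Atom keys: element.context; bond keys: bond.<order>.
key,value
C.sp3,5
C.sp2,3
C.sp,1
C.ar,6
N.sp3,6
N.sp2,5
N.ar,7
O.sp3,8
O.sp2,10
S.sp3,4
S.ar,5
P.sp3,3
F.sp3,6
Cl.sp3,4
Br.sp3,3
I.sp3,2
B.sp3,2
C,5
N,6
O,8
S,4
P,3
F,6
Cl,4
Br,3
I,2
B,2
bond.single,2
bond.double,5
bond.aromatic,4
bond.triple,3
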