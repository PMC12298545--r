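# Atom-contribution hydrophobicity increments (dimensionless, logP-like).
# key = element.context (context: sp/sp2/sp3 hybridization or .ar aromatic);
# bare-element rows are fallbacks.
key,value
C.sp3,0.5
C.sp2,0.4
C.sp,0.3
C.ar,0.3
N.sp3,-0.8
N.sp2,-0.6
N.ar,-0.5
O.sp3,-0.7
O.sp2,-0.6
S.sp3,-0.1
S.ar,0.0
P.sp3,-0.5
F.sp3,0.4
Cl.sp3,0.6
Br.sp3,0.8
I.sp3,0.9
B.sp3,0.2
C,0.5
N,-0.8
O,-0.7
S,-0.1
P,-0.5
F,0.4
Cl,0.6
Br,0.8
I,0.9
B,0.2
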