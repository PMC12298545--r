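# Glass-transition group contributions Y_g (K * kg/mol) per heavy atom;
# Tg estimate = 1000 * sum(Y_g) / M with M in g/mol. Calibrated so that
# common repeat units land near literature Tg ranges (polyethylene ~195 K,
# poly(ethylene oxide) ~195 K, polystyrene ~340 K).
key,value
C.sp3,2.8
C.sp2,4.0
C.sp,4.0
C.ar,5.0
N.sp3,4.0
N.sp2,4.5
N.ar,5.0
O.sp3,3.0
O.sp2,4.0
S.sp3,4.0
S.ar,4.5
P.sp3,3.0
F.sp3,1.0
Cl.sp3,3.5
Br.sp3,4.0
I.sp3,5.0
B.sp3,2.0
C,2.8
N,4.0
O,3.0
S,4.0
P,3.0
F,1.0
Cl,3.5
Br,4.0
I,5.0
B,2.0
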