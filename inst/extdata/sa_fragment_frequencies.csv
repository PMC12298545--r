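# Radius-1 atom-environment frequencies from the packaged reference corpus
# (300 seeded rollouts over the default toy library); used by sa_score().
key,value
248715136,641
20704826,528
621191390,499
700793781,405
22551868,389
20734617,358
492360120,238
87686820,190
248685314,154
248685345,150
22522077,121
621161599,115
1267692423,114
49363768,113
729422932,113
897033420,90
51181019,89
22522108,87
2139559322,83
25322431,80
1239063272,70
51151259,63
864837366,63
1720852736,63
52104540,54
53951582,46
1298168616,46
1269539465,45
700763991,44
864866165,35
51151228,33
248715105,33
1298138825,33
2139589113,32
1267722214,31
893466517,29
621192351,28
1270433226,28
700793782,26
973403321,20
863019123,14
700794742,10
50287600,6
973373530,6
50317391,3
700823573,3
729422933,3
922095668,3
973433112,3
1887055803,3
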