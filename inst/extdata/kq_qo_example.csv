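chamber,r50_cm,kq_qo
PTW 30013,3.84,0.911
PTW 30013,4.002,0.911
PTW 30013,4.68,0.908
PTW 30013,4.75,0.908
PTW 30013,5.76,0.905
PTW 30013,5.955,0.904
IBA CC13,3.84,0.920
IBA CC13,4.002,0.920
IBA CC13,4.68,0.918
IBA CC13,4.75,0.918
IBA CC13,5.76,0.914
IBA CC13,5.955,0.913
Exradin A1Sl,3.84,0.914
Exradin A1Sl,4.002,0.914
Exradin A1Sl,4.68,0.913
Exradin A1Sl,4.75,0.913
Exradin A1Sl,5.76,0.912
Exradin A1Sl,5.955,0.912
Exradin A11,2.37,0.932
Exradin A11,2.484,0.930
Exradin A11,3.17,0.921
Exradin A11,3.231,0.921
Exradin A11,3.84,0.915
Exradin A11,4.002,0.913
Exradin A11,4.68,0.907
Exradin A11,4.75,0.906
Exradin A11,5.76,0.899
Exradin A11,5.955,0.897
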