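tl_class,season,bf_thousands,stage_label,pf_thousands,batches,duration_months
40-50,SS3,142,VTO,283,2,0.3
40-50,SS3,142,+EVTO,567,4,0.5
40-50,SS3,142,+CA,850,6,0.8
40-50,SS3,142,+PVO4c,1417,10,1.3
40-50,SS3,142,+PVO4b,1700,12,1.6
40-50,SS3,142,+PVO4a,3401,24,3.2
40-50,SS3,142,+PVO1-3,10202,72,9.6
50-60,SS1,125,VTO,249,2,0.3
50-60,SS1,125,+EVTO,498,4,0.5
50-60,SS1,125,+CA,995,8,1.1
50-60,SS1,125,+PVO4c,1742,14,1.9
50-60,SS1,125,+PVO4b,2737,22,2.9
50-60,SS1,125,+PVO4a,3981,32,4.3
50-60,SS1,125,+PVO1-3,7713,62,8.3
50-60,SS2,177,VTO,353,2,0.3
50-60,SS2,177,+EVTO,706,4,0.5
50-60,SS2,177,+CA,1059,6,0.8
50-60,SS2,177,+PVO4c,1764,10,1.3
50-60,SS2,177,+PVO4b,2823,16,2.1
50-60,SS2,177,+PVO4a,4235,24,3.2
50-60,SS2,177,+PVO1-3,8469,48,6.4
50-60,SS3,128,VTO,255,2,0.3
50-60,SS3,128,+EVTO,511,4,0.5
50-60,SS3,128,+CA,766,6,0.8
50-60,SS3,128,+PVO4c,1277,10,1.3
50-60,SS3,128,+PVO4b,2042,16,2.1
50-60,SS3,128,+PVO4a,3064,24,3.2
50-60,SS3,128,+PVO1-3,9702,76,10
60-70,SS1,306,VTO,612,2,0.3
60-70,SS1,306,+EVTO,1225,4,0.5
60-70,SS1,306,+CA,1837,6,0.8
60-70,SS1,306,+PVO4c,3062,10,1.3
60-70,SS1,306,+PVO4b,4900,16,2.1
60-70,SS1,306,+PVO4a,6737,22,2.9
60-70,SS1,306,+PVO1-3,11637,38,5.1
60-70,SS2,188,VTO,375,2,0.3
60-70,SS2,188,+EVTO,749,4,0.5
60-70,SS2,188,+CA,1498,8,1.1
60-70,SS2,188,+PVO4c,2622,14,1.9
60-70,SS2,188,+PVO4b,4869,26,3.5
60-70,SS2,188,+PVO4a,6742,36,4.8
60-70,SS2,188,+PVO1-3,11985,64,8.5
60-70,SS3,157,VTO,313,2,0.3
60-70,SS3,157,+EVTO,626,4,0.5
60-70,SS3,157,+CA,1253,8,1.1
60-70,SS3,157,+PVO4c,1879,12,1.6
60-70,SS3,157,+PVO4b,3758,24,3.2
60-70,SS3,157,+PVO4a,5323,34,4.5
60-70,SS3,157,+PVO1-3,12525,80,11
70-80,SS1,393,VTO,786,2,0.3
70-80,SS1,393,+EVTO,1572,4,0.5
70-80,SS1,393,+CA,2357,6,0.8
70-80,SS1,393,+PVO4c,3929,10,1.3
70-80,SS1,393,+PVO4b,7072,18,2.4
70-80,SS1,393,+PVO4a,9430,24,3.2
70-80,SS1,393,+PVO1-3,14930,38,5.1
70-80,SS2,290,VTO,579,2,0.3
70-80,SS2,290,+EVTO,1158,4,0.5
70-80,SS2,290,+CA,2317,8,1.1
70-80,SS2,290,+PVO4c,3475,12,1.6
70-80,SS2,290,+PVO4b,6950,24,3.2
70-80,SS2,290,+PVO4a,9845,34,4.5
70-80,SS2,290,+PVO1-3,18532,64,8.5
70-80,SS3,462,VTO,924,2,0.3
70-80,SS3,462,+EVTO,1847,4,0.5
70-80,SS3,462,+CA,2771,6,0.8
70-80,SS3,462,+PVO4c,3694,8,1.1
70-80,SS3,462,+PVO4b,5541,12,1.6
70-80,SS3,462,+PVO4a,9236,20,2.7
70-80,SS3,462,+PVO1-3,22166,48,6.4
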