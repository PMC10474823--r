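species,n,method,mean,sd,printed_cv,printed_pct_diff
Archilochus colubris,17,spread,13.5,1.47,10.9,NA
Archilochus colubris,17,triangle,11.0,1.08,9.8,-19.1
Archilochus colubris,17,ellipse,14.9,1.38,9.3,9.8
Archilochus colubris,17,ellipse-triangle,13.6,1.28,9.4,0.2
Columba livia,18,spread,661.0,42.8,6.5,NA
Columba livia,18,triangle,536.3,27.3,5.1,-18.9
Columba livia,18,ellipse,689.4,33.9,4.9,4.3
Columba livia,18,ellipse-triangle,638.4,31.5,4.9,-3.4
Cyanocitta cristata,16,spread,365.8,20.7,5.7,NA
Cyanocitta cristata,16,triangle,305.6,13.0,4.3,-16.5
Cyanocitta cristata,16,ellipse,386.1,15.4,4.0,5.6
Cyanocitta cristata,16,ellipse-triangle,359.3,14.6,4.1,-1.8
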