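set,gene_id
s,Smarker01
s,Smarker02
s,Smarker03
s,Smarker04
s,Smarker05
s,Smarker06
s,Smarker07
s,Smarker08
s,Smarker09
s,Smarker10
s,Smarker11
s,Smarker12
s,Smarker13
s,Smarker14
s,Smarker15
s,Smarker16
s,Smarker17
s,Smarker18
s,Smarker19
s,Smarker20
g2m,G2mMarker01
g2m,G2mMarker02
g2m,G2mMarker03
g2m,G2mMarker04
g2m,G2mMarker05
g2m,G2mMarker06
g2m,G2mMarker07
g2m,G2mMarker08
g2m,G2mMarker09
g2m,G2mMarker10
g2m,G2mMarker11
g2m,G2mMarker12
g2m,G2mMarker13
g2m,G2mMarker14
g2m,G2mMarker15
g2m,G2mMarker16
g2m,G2mMarker17
g2m,G2mMarker18
g2m,G2mMarker19
g2m,G2mMarker20
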