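# Curated non-centrosymmetric space-group operator table.
# One group per block: "group <Hermann-Mauguin symbol> <lattice system>"
# followed by one symmetry operation per line in xyz-triplet notation.
# Centring translations are written out as explicit operations, so the
# operator list always generates the full unit-cell content.
group P1 triclinic
x,y,z
group P21 monoclinic
x,y,z
-x,y+1/2,-z
group C2 monoclinic
x,y,z
-x,y,-z
x+1/2,y+1/2,z
-x+1/2,y+1/2,-z
group P212121 orthorhombic
x,y,z
x+1/2,-y+1/2,-z
-x,y+1/2,-z+1/2
-x+1/2,-y,z+1/2
group P31 trigonal
x,y,z
-y,x-y,z+1/3
-x+y,-x,z+2/3
group R3 trigonal
x,y,z
-y,x-y,z
-x+y,-x,z
x+1/3,y+2/3,z+2/3
-y+1/3,x-y+2/3,z+2/3
-x+y+1/3,-x+2/3,z+2/3
x+2/3,y+1/3,z+1/3
-y+2/3,x-y+1/3,z+1/3
-x+y+2/3,-x+1/3,z+1/3
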