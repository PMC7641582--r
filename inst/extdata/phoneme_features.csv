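phoneme,components,voiced,unvoiced,bilabial,labiodental_dental,alveolar,velar,plosive,nasal,fricative,liquid,front,central,back
p,,0,1,1,0,0,0,1,0,0,0,0,0,0
b,,1,0,1,0,0,0,1,0,0,0,0,0,0
t,,0,1,0,0,1,0,1,0,0,0,0,0,0
d,,1,0,0,0,1,0,1,0,0,0,0,0,0
k,,0,1,0,0,0,1,1,0,0,0,0,0,0
g,,1,0,0,0,0,1,1,0,0,0,0,0,0
m,,1,0,1,0,0,0,0,1,0,0,0,0,0
n,,1,0,0,0,1,0,0,1,0,0,0,0,0
ng,,1,0,0,0,0,1,0,1,0,0,0,0,0
f,,0,1,0,1,0,0,0,0,1,0,0,0,0
v,,1,0,0,1,0,0,0,0,1,0,0,0,0
th,,0,1,0,1,0,0,0,0,1,0,0,0,0
dh,,1,0,0,1,0,0,0,0,1,0,0,0,0
s,,0,1,0,0,1,0,0,0,1,0,0,0,0
z,,1,0,0,0,1,0,0,0,1,0,0,0,0
sh,,0,1,0,0,1,0,0,0,1,0,0,0,0
zh,,1,0,0,0,1,0,0,0,1,0,0,0,0
hh,,0,1,0,0,0,0,0,0,1,0,0,0,0
ch,t sh,,,,,,,,,,,,,
jh,d zh,,,,,,,,,,,,,
l,,1,0,0,0,1,0,0,0,0,1,0,0,0
r,,1,0,0,0,1,0,0,0,0,1,0,0,0
w,,1,0,1,0,0,0,0,0,0,1,0,0,0
y,,1,0,0,0,0,0,0,0,0,1,1,0,0
iy,,1,0,0,0,0,0,0,0,0,0,1,0,0
ih,,1,0,0,0,0,0,0,0,0,0,1,0,0
eh,,1,0,0,0,0,0,0,0,0,0,1,0,0
ae,,1,0,0,0,0,0,0,0,0,0,1,0,0
aa,,1,0,0,0,0,0,0,0,0,0,0,0,1
ah,,1,0,0,0,0,0,0,0,0,0,0,1,0
ao,,1,0,0,0,0,0,0,0,0,0,0,0,1
uh,,1,0,0,0,0,0,0,0,0,0,0,0,1
uw,,1,0,0,0,0,0,0,0,0,0,0,0,1
er,,1,0,0,0,0,0,0,0,0,0,0,1,0
ey,eh iy,,,,,,,,,,,,,
ay,aa iy,,,,,,,,,,,,,
oy,ao iy,,,,,,,,,,,,,
aw,aa uw,,,,,,,,,,,,,
ow,ah uw,,,,,,,,,,,,,
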