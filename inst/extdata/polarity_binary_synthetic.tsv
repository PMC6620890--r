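term	value
bueno	1
genial	1
maravilloso	1
excelente	1
estupendo	1
precioso	1
fantástico	1
agradable	1
bonito	1
perfecto	1
encantador	1
magnífico	1
malo	-1
horrible	-1
terrible	-1
fatal	-1
espantoso	-1
odioso	-1
desagradable	-1
feo	-1
pésimo	-1
atroz	-1
lamentable	-1
nefasto	-1
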