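term	value
sublime	0.8
glorioso	0.8
espléndido	0.8
radiante	0.8
aceptable	0.3
decente	0.3
correcto	0.3
apañado	0.3
mediocre	-0.3
flojo	-0.3
soso	-0.3
insulso	-0.3
desastroso	-0.8
infame	-0.8
deplorable	-0.8
ruinoso	-0.8
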