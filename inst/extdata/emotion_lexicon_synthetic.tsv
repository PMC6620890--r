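term	emotion
alegría	happiness
felicidad	happiness
contento	happiness
risa	happiness
tristeza	sadness
pena	sadness
melancolía	sadness
llanto	sadness
enojo	anger
rabia	anger
furioso	anger
ira	anger
miedo	fear
temor	fear
pánico	fear
asustado	fear
asco	disgust
repulsión	disgust
repugnante	disgust
náusea	disgust
sorpresa	surprise
asombro	surprise
asombrado	surprise
inesperado	surprise
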