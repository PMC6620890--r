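word	pos	person
casa	noun	
tiempo	noun	
vida	noun	
día	noun	
noche	noun	
mundo	noun	
gente	noun	
cosa	noun	
año	noun	
momento	noun	
trabajo	noun	
ciudad	noun	
amigo	noun	
familia	noun	
música	noun	
foto	noun	
juego	noun	
libro	noun	
calle	noun	
cielo	noun	
mano	noun	
corazón	noun	
palabra	noun	
semana	noun	
hora	noun	
camino	noun	
puerta	noun	
mesa	noun	
perro	noun	
gato	noun	
ansiedad	noun	
depresión	noun	
insomnio	noun	
depre	noun	
alegría	noun	
felicidad	noun	
risa	noun	
tristeza	noun	
pena	noun	
melancolía	noun	
llanto	noun	
enojo	noun	
rabia	noun	
ira	noun	
miedo	noun	
temor	noun	
pánico	noun	
asco	noun	
repulsión	noun	
náusea	noun	
sorpresa	noun	
asombro	noun	
ser	verb	
estar	verb	
tener	verb	
hacer	verb	
poder	verb	
decir	verb	
ir	verb	
ver	verb	
dar	verb	
saber	verb	
querer	verb	
llegar	verb	
pasar	verb	
deber	verb	
poner	verb	
parecer	verb	
quedar	verb	
creer	verb	
hablar	verb	
llevar	verb	
dejar	verb	
seguir	verb	
encontrar	verb	
llamar	verb	
venir	verb	
pensar	verb	
salir	verb	
volver	verb	
tomar	verb	
conocer	verb	
llorar	verb	
yo	pronoun	1S
me	pronoun	1S
mí	pronoun	1S
conmigo	pronoun	1S
nosotros	pronoun	1P
nosotras	pronoun	1P
nos	pronoun	1P
tú	pronoun	2S
te	pronoun	2S
ti	pronoun	2S
vos	pronoun	2S
usted	pronoun	2S
vosotros	pronoun	2P
vosotras	pronoun	2P
os	pronoun	2P
ustedes	pronoun	2P
él	pronoun	3S
ella	pronoun	3S
ello	pronoun	3S
se	pronoun	3S
lo	pronoun	3S
la	pronoun	3S
le	pronoun	3S
ellos	pronoun	3P
ellas	pronoun	3P
los	pronoun	3P
las	pronoun	3P
les	pronoun	3P
esto	pronoun	
eso	pronoun	
aquello	pronoun	
algo	pronoun	
alguien	pronoun	
quien	pronoun	
cual	pronoun	
otro	pronoun	
demasiados	pronoun	
grande	adjective	
pequeño	adjective	
nuevo	adjective	
viejo	adjective	
joven	adjective	
alto	adjective	
bajo	adjective	
largo	adjective	
corto	adjective	
fácil	adjective	
difícil	adjective	
rápido	adjective	
lento	adjective	
claro	adjective	
oscuro	adjective	
fuerte	adjective	
débil	adjective	
lleno	adjective	
abierto	adjective	
cerrado	adjective	
agobiado	adjective	
agobiada	adjective	
agotado	adjective	
agotada	adjective	
angustiado	adjective	
angustiada	adjective	
ansioso	adjective	
ansiosa	adjective	
cansado	adjective	
cansada	adjective	
decaído	adjective	
depresivo	adjective	
depresiva	adjective	
deprimido	adjective	
deprimida	adjective	
desanimado	adjective	
desanimada	adjective	
desesperado	adjective	
desesperada	adjective	
desmotivado	adjective	
desmotivada	adjective	
nervioso	adjective	
preocupado	adjective	
preocupada	adjective	
solo	adjective	
sola	adjective	
triste	adjective	
vacío	adjective	
vacía	adjective	
contento	adjective	
furioso	adjective	
asustado	adjective	
repugnante	adjective	
asombrado	adjective	
inesperado	adjective	
bueno	adjective	
genial	adjective	
maravilloso	adjective	
excelente	adjective	
estupendo	adjective	
precioso	adjective	
fantástico	adjective	
agradable	adjective	
bonito	adjective	
perfecto	adjective	
encantador	adjective	
magnífico	adjective	
malo	adjective	
horrible	adjective	
terrible	adjective	
fatal	adjective	
espantoso	adjective	
odioso	adjective	
desagradable	adjective	
feo	adjective	
pésimo	adjective	
atroz	adjective	
lamentable	adjective	
nefasto	adjective	
sublime	adjective	
glorioso	adjective	
espléndido	adjective	
radiante	adjective	
aceptable	adjective	
decente	adjective	
correcto	adjective	
apañado	adjective	
mediocre	adjective	
flojo	adjective	
soso	adjective	
insulso	adjective	
desastroso	adjective	
infame	adjective	
deplorable	adjective	
ruinoso	adjective	
el	determiner	
un	determiner	
una	determiner	
unos	determiner	
unas	determiner	
este	determiner	
esta	determiner	
estos	determiner	
estas	determiner	
ese	determiner	
esa	determiner	
aquel	determiner	
aquella	determiner	
mi	determiner	
su	determiner	
mis	determiner	
sus	determiner	
cada	determiner	
alguna	determiner	
cualquier	determiner	
muy	adverb	
bien	adverb	
mal	adverb	
hoy	adverb	
ahora	adverb	
siempre	adverb	
después	adverb	
antes	adverb	
aquí	adverb	
allí	adverb	
así	adverb	
también	adverb	
ya	adverb	
casi	adverb	
luego	adverb	
pronto	adverb	
tarde	adverb	
cerca	adverb	
lejos	adverb	
quizás	adverb	
no	adverb	
nada	adverb	
nadie	adverb	
nunca	adverb	
jamás	adverb	
ni	adverb	
ningún	adverb	
ninguno	adverb	
ninguna	adverb	
tampoco	adverb	
sin	adverb	
de	adposition	
a	adposition	
en	adposition	
con	adposition	
por	adposition	
para	adposition	
entre	adposition	
hasta	adposition	
desde	adposition	
sobre	adposition	
tras	adposition	
durante	adposition	
mediante	adposition	
contra	adposition	
hacia	adposition	
y	conjunction	
o	conjunction	
pero	conjunction	
porque	conjunction	
aunque	conjunction	
cuando	conjunction	
si	conjunction	
pues	conjunction	
mientras	conjunction	
sino	conjunction	
como	conjunction	
que	conjunction	
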