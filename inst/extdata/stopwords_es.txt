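de
la
que
el
en
y
a
los
se
del
las
un
por
con
no
una
su
para
es
al
lo
como
más
pero
sus
le
ya
o
fue
este
ha
sí
porque
esta
son
entre
está
cuando
muy
sin
sobre
ser
tiene
también
me
hasta
hay
donde
han
quien
están
estado
desde
todo
nos
durante
todos
uno
les
ni
contra
otros
fueron
ese
eso
había
ante
ellos
e
esto
mí
antes
algunos
qué
unos
yo
otro
otras
otra
él
tanto
esa
estos
mucho
quienes
nada
muchos
cual
sea
poco
ella
estar
haber
estas
estaba
estamos
algunas
algo
nosotros
mi
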