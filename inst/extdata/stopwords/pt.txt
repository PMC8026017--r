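# Portuguese function words: articles, prepositions (incl. contractions),
# conjunctions, common pronouns and other liaison terms of oral speech.
a
à
às
ao
aos
aquela
aquelas
aquele
aqueles
aquilo
as
até
com
como
contra
da
daquela
daquele
das
de
dela
delas
dele
deles
depois
desde
dessa
desse
desta
deste
disso
disto
do
dos
duma
dumas
dum
duns
e
é
ela
elas
ele
eles
em
então
entre
era
eram
essa
essas
esse
esses
esta
estas
este
estes
eu
foi
for
foram
há
isso
isto
já
la
lá
lhe
lhes
lo
mas
me
mesma
mesmo
meu
minha
muito
na
nas
nem
no
nos
nós
nossa
nosso
num
numa
o
os
ou
para
pela
pelas
pelo
pelos
pois
por
porque
pra
qual
quando
que
quem
se
sem
ser
seu
seus
sua
suas
são
só
também
te
tem
teu
tua
tu
um
uma
umas
uns
você
vocês
vos
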