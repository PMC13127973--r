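# Default Italian function-word list for sentence-embedding cohesion.
# Replaceable: pass any one-token-per-line file instead.
a
ad
al
allo
ai
agli
all
alla
alle
con
col
coi
da
dal
dallo
dai
dagli
dall
dalla
dalle
di
del
dello
dei
degli
dell
della
delle
in
nel
nello
nei
negli
nell
nella
nelle
su
sul
sullo
sui
sugli
sull
sulla
sulle
per
tra
fra
contro
io
tu
lui
lei
noi
voi
loro
mio
mia
miei
mie
tuo
tua
tuoi
tue
suo
sua
suoi
sue
nostro
nostra
nostri
nostre
vostro
vostra
vostri
vostre
mi
ti
ci
vi
lo
la
li
le
gli
ne
il
un
uno
una
ma
ed
se
perche
anche
come
dov
dove
che
chi
cui
non
piu
quale
quanto
quanti
quanta
quante
quello
quelli
quella
quelle
questo
questi
questa
queste
si
tutto
tutti
e
sono
sei
siamo
siete
sia
siate
essendo
ho
hai
ha
abbiamo
avete
hanno
avendo
avuto
era
eravamo
erano
fu
furono
sara
saranno
sarebbe
stato
stata
stati
state
sto
sta
stanno
o
od
ancora
allora
avere
essere
fare
quindi
pero
senza
dopo
prima
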