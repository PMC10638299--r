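# Spanish toy lexicon: surface<TAB>pos<TAB>lemma
# Deterministic test-double for a pretrained tagger; coverage is the
# frequent vocabulary of dream journals plus common function words.
a	ADP	a
abrir	VERB	abrir
abrí	VERB	abrir
abuela	NOUN	abuela
agua	NOUN	agua
aire	NOUN	aire
al	ADP	al
alegría	NOUN	alegría
alto	ADJ	alto
amigo	NOUN	amigo
angustia	NOUN	angustia
animal	NOUN	animal
azul	ADJ	azul
bajar	VERB	bajar
bajé	VERB	bajar
beber	VERB	beber
blanco	ADJ	blanco
bonito	ADJ	bonito
brazo	NOUN	brazo
buscar	VERB	buscar
busqué	VERB	buscar
cabeza	NOUN	cabeza
caer	VERB	caer
calle	NOUN	calle
cama	NOUN	cama
caminaba	VERB	caminar
caminar	VERB	caminar
camino	NOUN	camino
campo	NOUN	campo
cara	NOUN	cara
casa	NOUN	casa
casas	NOUN	casa
caí	VERB	caer
cerrar	VERB	cerrar
cerré	VERB	cerrar
cielo	NOUN	cielo
ciudad	NOUN	ciudad
claro	ADJ	claro
coche	NOUN	coche
color	NOUN	color
comer	VERB	comer
como	SCONJ	como
con	ADP	con
correr	VERB	correr
corría	VERB	correr
cosa	NOUN	cosa
creer	VERB	creer
cuando	SCONJ	cuando
cuerpo	NOUN	cuerpo
cuerpos	NOUN	cuerpo
daba	VERB	dar
dar	VERB	dar
de	ADP	de
decir	VERB	decir
decía	VERB	decir
dejar	VERB	dejar
del	ADP	del
despertar	VERB	despertar
desperté	VERB	despertar
despierto	ADJ	despierto
di	VERB	dar
digo	VERB	decir
dije	VERB	decir
dormido	ADJ	dormido
dormir	VERB	dormir
dormía	VERB	dormir
doy	VERB	dar
duermo	VERB	dormir
día	NOUN	día
edificio	NOUN	edificio
el	DET	el
empezar	VERB	empezar
en	ADP	en
encontrar	VERB	encontrar
encontré	VERB	encontrar
entonces	ADV	entonces
entrar	VERB	entrar
entré	VERB	entrar
era	VERB	ser
es	VERB	ser
escalera	NOUN	escalera
escribir	VERB	escribir
escuchar	VERB	escuchar
escuela	NOUN	escuela
espejo	NOUN	espejo
estaba	VERB	estar
estar	VERB	estar
estoy	VERB	estar
estudiar	VERB	estudiar
estuve	VERB	estar
extraña	ADJ	extraño
extraño	ADJ	extraño
familia	NOUN	familia
feo	ADJ	feo
forma	NOUN	forma
fue	VERB	ser
fuego	NOUN	fuego
fuerte	ADJ	fuerte
fui	VERB	ir
gato	NOUN	gato
gente	NOUN	gente
grande	ADJ	grande
grandes	ADJ	grande
gritar	VERB	gritar
haber	VERB	haber
habitaciones	NOUN	habitación
habitación	NOUN	habitación
hablaba	VERB	hablar
hablar	VERB	hablar
había	VERB	haber
hacer	VERB	hacer
hacía	VERB	hacer
hago	VERB	hacer
hay	VERB	haber
he	VERB	haber
hermano	NOUN	hermano
hice	VERB	hacer
hombre	NOUN	hombre
iba	VERB	ir
intentar	VERB	intentar
ir	VERB	ir
jugar	VERB	jugar
la	DET	la
las	DET	las
leer	VERB	leer
lento	ADJ	lento
llegar	VERB	llegar
llego	VERB	llegar
llegué	VERB	llegar
llevar	VERB	llevar
llorar	VERB	llorar
lo	PRON	lo
lograr	VERB	lograr
los	DET	los
lugar	NOUN	lugar
luz	NOUN	luz
madre	NOUN	madre
mano	NOUN	mano
manos	NOUN	mano
mar	NOUN	mar
me	PRON	me
mi	DET	mi
miedo	NOUN	miedo
mirar	VERB	mirar
miro	VERB	mirar
miré	VERB	mirar
momento	NOUN	momento
montaña	NOUN	montaña
morir	VERB	morir
mujer	NOUN	mujer
muy	ADV	muy
negro	ADJ	negro
niño	NOUN	niño
no	ADV	no
noche	NOUN	noche
nuevo	ADJ	nuevo
ojo	NOUN	ojo
ojos	NOUN	ojo
oscura	ADJ	oscuro
oscuro	ADJ	oscuro
padre	NOUN	padre
para	ADP	para
pared	NOUN	pared
pasar	VERB	pasar
paso	VERB	pasar
pasó	VERB	pasar
paz	NOUN	paz
pelo	NOUN	pelo
pensaba	VERB	pensar
pensar	VERB	pensar
pequeño	ADJ	pequeño
perder	VERB	perder
perdí	VERB	perder
pero	CCONJ	pero
perro	NOUN	perro
persona	NOUN	persona
personas	NOUN	persona
pie	NOUN	pie
poder	VERB	poder
podía	VERB	poder
por	ADP	por
pude	VERB	poder
puedo	VERB	poder
puerta	NOUN	puerta
pájaro	NOUN	pájaro
que	SCONJ	que
querer	VERB	querer
quería	VERB	querer
quiero	VERB	querer
raro	ADJ	raro
real	ADJ	real
recordar	VERB	recordar
recordé	VERB	recordar
recuerdo	VERB	recordar
reír	VERB	reír
rojo	ADJ	rojo
ruido	NOUN	ruido
rápido	ADJ	rápido
saber	VERB	saber
sabía	VERB	saber
salgo	VERB	salir
saliendo	VERB	salir
salir	VERB	salir
salí	VERB	salir
se	PRON	se
sensación	NOUN	sensación
sentir	VERB	sentir
sentí	VERB	sentir
ser	VERB	ser
siento	VERB	sentir
silencio	NOUN	silencio
sombra	NOUN	sombra
soy	VERB	ser
soñando	VERB	soñar
soñar	VERB	soñar
soñé	VERB	soñar
su	DET	su
subir	VERB	subir
subí	VERB	subir
suelo	NOUN	suelo
sueño	NOUN	sueño
sueños	NOUN	sueño
sé	VERB	saber
techo	NOUN	techo
terminar	VERB	terminar
tiempo	NOUN	tiempo
tierra	NOUN	tierra
tomar	VERB	tomar
trabajar	VERB	trabajar
traer	VERB	traer
tristeza	NOUN	tristeza
un	DET	un
una	DET	una
ventana	NOUN	ventana
veo	VERB	ver
ver	VERB	ver
verde	ADJ	verde
veía	VERB	ver
vi	VERB	ver
viaje	NOUN	viaje
viejo	ADJ	viejo
viento	NOUN	viento
visto	VERB	ver
vivir	VERB	vivir
volaba	VERB	volar
volar	VERB	volar
volver	VERB	volver
volví	VERB	volver
volé	VERB	volar
voy	VERB	ir
voz	NOUN	voz
vuelo	NOUN	vuelo
y	CCONJ	y
árbol	NOUN	árbol
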