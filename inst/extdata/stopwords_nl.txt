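# Dutch stop words (function words; intensifiers and negators included,
# which is why the sentiment stage keeps them in the token stream)
de
het
een
en
van
ik
dat
die
in
te
is
op
niet
met
als
voor
maar
er
aan
bij
ook
dan
zijn
naar
heb
wordt
dit
mij
mijn
door
om
uit
over
geen
wel
na
nog
al
tot
deze
of
je
ze
we
me
hij
zij
wat
worden
kan
kunnen
heeft
had
hebben
moet
dus
toch
heel
zeer
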