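word	valence
love	3.2
loved	2.9
loves	2.7
loving	2.9
adore	2.9
amazing	2.8
awesome	3.1
excellent	2.7
fantastic	2.6
wonderful	2.7
great	3.1
good	1.9
nice	1.8
sweet	2.0
happy	2.7
happiness	2.6
joy	2.8
joyful	2.9
glad	2.0
grateful	2.4
thankful	2.3
proud	2.1
calm	1.3
peaceful	2.2
relaxed	1.8
relax	1.5
hope	1.9
hopeful	2.3
optimistic	2.4
confident	2.2
better	1.9
best	3.2
beautiful	2.9
brilliant	2.8
celebrate	2.7
comfort	1.9
comfortable	1.9
courage	2.2
delight	2.9
eager	1.6
easy	1.5
encourage	2.3
enjoy	2.2
enjoyed	2.3
excited	2.2
excitement	2.4
fine	0.8
free	1.9
freedom	2.6
friendly	2.2
fun	2.3
funny	1.9
gain	1.4
generous	2.3
gentle	1.9
gift	1.9
glorious	2.8
grace	1.7
heal	2.0
healthy	2.0
helpful	1.9
honest	2.2
improve	1.9
improved	2.1
inspire	2.6
interested	1.7
interesting	1.7
kind	2.4
laugh	2.6
laughed	2.2
like	1.5
liked	1.8
lucky	2.4
perfect	2.7
pleasant	2.3
pleased	2.3
pleasure	2.7
positive	2.3
pretty	2.2
recover	1.5
recovery	1.8
relief	2.1
relieved	2.2
respect	2.1
reward	2.2
safe	1.9
satisfied	2.0
secure	1.7
smile	2.3
smiled	2.1
strong	2.3
succeed	2.5
success	2.7
successful	2.8
support	1.7
supportive	2.2
thank	1.9
thanks	1.9
therapy	0.6
trust	2.1
useful	1.9
victory	2.8
warm	1.6
welcome	2.0
well	1.1
win	2.8
winner	2.8
wise	2.1
worthy	1.9
yes	1.2
hate	-2.7
hated	-2.9
hates	-2.6
hateful	-2.8
awful	-2.0
terrible	-2.1
horrible	-2.5
horrific	-3.0
bad	-2.5
worse	-2.1
worst	-3.1
sad	-2.1
sadness	-2.0
unhappy	-1.8
miserable	-2.7
depressed	-2.3
depressing	-1.9
depression	-2.2
anxious	-1.9
anxiety	-1.8
nervous	-1.2
worried	-1.3
worry	-1.3
worrying	-1.4
afraid	-2.0
scared	-1.9
scary	-2.2
fear	-2.2
fearful	-2.1
terrified	-2.8
terror	-3.1
panic	-2.4
dread	-2.2
stress	-1.8
stressed	-1.8
stressful	-1.9
angry	-2.3
anger	-2.5
mad	-2.2
furious	-2.7
rage	-2.5
annoyed	-1.6
annoying	-1.8
irritated	-1.8
hostile	-2.2
bitter	-1.8
cry	-1.9
crying	-2.0
cried	-1.9
tears	-1.2
grief	-2.3
mourn	-2.4
lonely	-2.1
loneliness	-2.2
alone	-1.0
isolated	-1.6
abandoned	-2.2
rejected	-2.1
hopeless	-2.5
helpless	-2.2
worthless	-2.7
useless	-2.1
failure	-2.4
failed	-2.1
fail	-2.0
lose	-1.6
lost	-1.4
loss	-1.7
hurt	-2.1
hurting	-2.2
pain	-2.2
painful	-2.3
suffer	-2.4
suffering	-2.5
ache	-1.6
sick	-1.7
sickness	-1.8
ill	-1.6
illness	-1.7
disease	-1.9
infected	-1.9
infection	-1.8
virus	-1.2
dying	-2.8
die	-2.7
died	-2.6
dead	-2.9
death	-2.7
kill	-3.1
killed	-3.0
suicide	-3.2
suicidal	-3.1
overdose	-2.8
abuse	-2.8
abused	-2.9
abusive	-2.9
violence	-2.9
violent	-2.6
attack	-2.1
threat	-2.2
danger	-2.2
dangerous	-2.3
crisis	-2.0
disaster	-2.5
tragedy	-2.9
trauma	-2.4
traumatic	-2.6
nightmare	-2.4
insomnia	-1.6
tired	-1.2
exhausted	-1.8
drained	-1.6
numb	-1.4
empty	-1.5
broken	-2.0
ruined	-2.3
wrong	-1.6
problem	-1.4
problems	-1.5
trouble	-1.6
struggle	-1.7
struggling	-1.8
difficult	-1.4
hard	-0.4
impossible	-1.5
can't	-0.9
no	-1.2
not	-0.7
never	-1.0
nothing	-1.1
nobody	-1.4
guilt	-2.0
guilty	-1.9
shame	-2.1
ashamed	-2.1
embarrassed	-1.6
disgust	-2.3
disgusting	-2.4
ugly	-2.1
nasty	-2.1
evil	-2.9
cruel	-2.6
selfish	-1.9
jealous	-1.7
envy	-1.5
regret	-1.8
sorry	-0.4
apolog	-0.3
upset	-1.7
frustrated	-1.9
frustrating	-1.9
overwhelmed	-1.7
confused	-1.2
doubt	-1.2
uncertain	-1.1
unstable	-1.6
paranoid	-2.0
delusion	-1.9
hallucination	-1.8
manic	-1.5
withdrawal	-1.8
relapse	-2.0
addicted	-2.1
addiction	-2.1
drunk	-1.4
hangover	-1.6
damn	-1.6
hell	-1.7
crap	-1.6
shit	-2.0
fuck	-2.3
fucking	-2.1
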