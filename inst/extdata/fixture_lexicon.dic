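%
1	i
2	we
3	shehe
4	they
5	you
6	article
7	prep
8	ppron
9	ipron
10	auxverb
11	conj
12	adverb
13	negate
14	tone_pos
15	tone_neg
16	Cognition
17	memory
18	focuspast
19	focuspresent
20	focusfuture
21	attention
22	visual
23	auditory
24	feeling
25	space
26	motion
27	time
28	Affect
%
a	6
about	7
above	25
ago	18
also	12
although	11
always	12
am	10	19
an	6
and	11
angry	15	28
anything	9
are	10	19
area*	25
around	25
arrive*	26
ashamed	28
assume*	16
at	7
attention	21
aware	21
awful	15
bad	15
be	10
beautiful	14
because	11	16
been	10
behind	25
being	10
believe*	16
below	25
best	14
between	7
blue	22
bright	22
but	11
by	7
came	18	26
can	10
can't	13
cannot	13
cold	24
color*	22
colour*	22
come	26
consider*	16
corner*	25
could	10
cry*	28
currently	19
dark	22
day	27
days	27
decide*	16
did	10	18
didn't	13
do	10
does	10
doing	19
don't	13
drive*	26
during	7
earlier	18
enjoy*	14
evening	27
everything	9
excited	28
far	25
fear*	15	28
feel*	24
felt	24
focus*	21
for	7
forget*	17
forgot	17
from	7
glad	14	28
glimpse*	22
go	26
going	20	26
gonna	20
good	14
great	14
green	22
guess*	16
had	10	18
happened	18
happens	19
happy	14	28
has	10
hate*	15	28
have	10
he	3	8
he's	3
hear*	23
heard	23
her	3	8
here	25
hers	3
herself	3
him	3	8
himself	3
his	3	8
horrible	15
hour*	27
i	1	8
i'd	1
i'll	1
i'm	1
i've	1
idea*	16
if	11
in	7
inside	25
insight*	16
into	7
is	10	19
isn't	13
it	9
it's	9
its	9
joy*	28
just	12
know*	16
later	20	27
laugh*	28
leave	26
left	26
listen*	23
look*	21
loud	23
love*	14	28
may	10
maybe	12
me	1	8
memories	17
memory	17
might	10
mine	1	8
minute*	27
moment*	27
month*	27
morning	27
move*	26
music	23
must	10
my	1	8
myself	1
near	25
never	12	13
nice	14
night	27
no	13
nobody	13
noise*	23
none	13
nostalgi*	17
not	13
nothing	9	13
notice*	21
now	19	27
observe*	21
of	7
often	12
on	7
or	11
our	2	8
ours	2	8
ourselves	2
outside	25
over	7
pain*	24
painful	15
perfect	14
place*	25
plan*	20
pleasant	14
present	19
proud	28
quickly	12
quiet	23
quite	12
rather	12
realize*	16
really	12
reason*	16
recall*	17
red	22
remember*	17
remind*	17
ride*	26
room*	25
rough	24
run*	26
sad	15	28
said	18
saw	18	22
see	22
seen	22
shall	10	20
she	3	8
she's	3
shiny	22
should	10
since	11
slowly	12
smooth	24
so	11
soft	24
something	9
soon	12	20
sound*	23
terrible	15
that	9
the	6
their	4	8
theirs	4
them	4	8
themselves	4
then	27
there	25
these	9
they	4	8
they're	4
think*	16
this	9
those	9
thought*	16
through	7
tingl*	24
to	7
today	19	27
tomorrow	20	27
too	12
touch*	24
travel*	26
ugly	15
under	7
understand*	16
unless	11
upcoming	20
upset	28
us	2	8
used	18
very	12
visible	22
voice*	23
walk*	26
warm	24
was	10	18
wasn't	13
watch*	21
we	2	8
we'll	2
we're	2
we've	2
week*	27
went	18	26
were	10	18
what	9
when	27
where	25
whereas	11
which	9
while	11
will	10	20
with	7
without	7
won't	13
wonder*	16
wonderful	14
worried	15	28
worst	15
would	10
year*	27
yesterday	18	27
you	5	8
you're	5
you've	5
your	5	8
yours	5
yourself	5
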