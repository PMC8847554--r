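%
1	first_singular
2	first_plural
3	second_person
4	third_person
5	positive_emotion
6	negative_emotion
7	swear
8	article
9	negation
%
i	1
me	1
my	1
mine	1
myself	1
we	2
our	2
us	2
ours	2
ourselves	2
you	3
your	3
yours	3
yourself	3
she	4
he	4
they	4
them	4
her	4
his	4
their	4
love	5
nice	5
good	5
great	5
happ*	5
joy*	5
hurt	6
ugly	6
bad	6
awful	6
sad*	6
terribl*	6
damn	7
crap	7
hell	7
dang	7
a	8
an	8
the	8
not	9
never	9
no	9
cant	9
dont	9
wont	9
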