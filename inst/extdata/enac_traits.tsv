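taxon	site1	site2	tandem	PY	terrestrial	lungs
S.Lamprey_alpha	0	0	0	0	0	0
J.Lamprey_alpha	0	0	0	1	0	0
E.Shark_alpha	?	?	?	?	0	0
Ropefish_alpha	0	0	0	1	0	1
Coelacanth_alpha	1	0	0	1	0	0
W.Lungfish_alpha	0	0	0	1	0	1
A.Lungfish_alpha	0	0	0	1	0	1
Frog_alpha	1	1	1	1	1	1
Salamander_alpha	1	1	1	1	1	1
Turtle_alpha	1	1	1	1	1	1
Chicken_alpha	1	1	1	1	1	1
Cow_alpha	1	1	1	1	1	1
Human_alpha	1	1	1	1	1	1
Coelacanth_delta	0	0	0	?	0	0
Frog_delta	0	0	0	0	1	1
Turtle_delta	0	0	0	0	1	1
Chicken_delta	0	0	0	0	1	1
Cow_delta	0	1	0	0	1	1
Human_delta	0	1	0	0	1	1
S.Lamprey_beta	0	0	0	1	0	0
J.Lamprey_beta	0	0	0	1	0	0
E.Shark_beta	0	0	0	1	0	0
Ropefish_beta	0	0	0	1	0	1
Coelacanth_beta	1	0	0	1	0	0
W.Lungfish_beta	0	0	0	1	0	1
A.Lungfish_beta	0	0	0	1	0	1
Frog_beta	0	0	0	1	1	1
Turtle_beta	0	0	0	1	1	1
Chicken_beta	0	0	0	1	1	1
Cow_beta	0	0	0	1	1	1
Human_beta	0	0	0	1	1	1
S.Lamprey_gamma	0	0	0	1	0	0
J.Lamprey_gamma	0	0	0	1	0	0
E.Shark_gamma	0	1	0	1	0	0
Ropefish_gamma	1	1	1	1	0	1
Coelacanth_gamma	0	1	0	1	0	0
W.Lungfish_gamma	0	0	0	1	0	1
A.Lungfish_gamma	1	1	1	1	0	1
Frog_gamma	1	1	1	1	1	1
Turtle_gamma	1	1	1	1	1	1
Chicken_gamma	1	1	1	1	1	1
Cow_gamma	1	1	1	1	1	1
Human_gamma	1	1	1	1	1	1
Human_ASIC1	0	0	0	0	0	0
Coelacanth_ASIC1	0	0	0	0	0	0
J.Medaka_ASIC1	0	0	0	0	0	0
Human_ASIC2	0	0	0	0	0	0
Coelacanth_ASIC2	0	1	0	0	0	0
E.Shark_ASIC1	0	0	0	0	0	0
J.Medaka_ENaClike1	0	0	0	0	0	0
J.Medaka_ENaClike2	0	0	0	0	0	0
Tunicate_ENaClike	0	0	0	0	0	0
Lancelet_ENaClike	0	0	0	0	0	0
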