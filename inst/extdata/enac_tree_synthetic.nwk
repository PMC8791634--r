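(((((S.Lamprey_beta:0.22,J.Lamprey_beta:0.22):0.385,(E.Shark_beta:0.506,(Ropefish_beta:0.473,(Coelacanth_beta:0.462,((W.Lungfish_beta:0.275,A.Lungfish_beta:0.275):0.176,(Frog_beta:0.385,((Turtle_beta:0.286,Chicken_beta:0.286):0.055,(Cow_beta:0.1045,Human_beta:0.1045):0.2365):0.044):0.066):0.011):0.011):0.033):0.099):0.033,((S.Lamprey_gamma:0.24,J.Lamprey_gamma:0.24):0.42,(E.Shark_gamma:0.552,(Ropefish_gamma:0.516,(Coelacanth_gamma:0.504,((W.Lungfish_gamma:0.3,A.Lungfish_gamma:0.3):0.192,(Frog_gamma:0.42,((Turtle_gamma:0.312,Chicken_gamma:0.312):0.06,(Cow_gamma:0.114,Human_gamma:0.114):0.258):0.048):0.072):0.012):0.012):0.036):0.108):0.036)node2:0.022,((S.Lamprey_alpha:0.26,J.Lamprey_alpha:0.26):0.468,(E.Shark_alpha:0.598,(Ropefish_alpha:0.585,((Coelacanth_alpha:0.546,((W.Lungfish_alpha:0.325,A.Lungfish_alpha:0.325):0.208,((Frog_alpha:0.377,Salamander_alpha:0.377):0.078,((Turtle_alpha:0.338,Chicken_alpha:0.338):0.065,(Cow_alpha:0.1235,Human_alpha:0.1235):0.2795):0.052):0.078):0.013):0.026,(Coelacanth_delta:0.714,(Frog_delta:0.595,((Turtle_delta:0.442,Chicken_delta:0.442):0.085,(Cow_delta:0.1615,Human_delta:0.1615):0.3655):0.068):0.119):0.034)node4:0.013):0.013):0.13)node3:0.052)node1:0.055,((((Human_ASIC1:0.378,Coelacanth_ASIC1:0.378):0.009,J.Medaka_ASIC1:0.387):0.063,((Human_ASIC2:0.378,Coelacanth_ASIC2:0.378):0.036,E.Shark_ASIC1:0.414):0.036):0.108,((J.Medaka_ENaClike1:0.48,J.Medaka_ENaClike2:0.48):0.48,(Tunicate_ENaClike:0.88,Lancelet_ENaClike:0.88):0.08):0.032):0.027);
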