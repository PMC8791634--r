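>S.Lamprey_alpha
PTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMPPPSF
>J.Lamprey_alpha
DGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEPPDY
>E.Shark_alpha
MQVDGLPTAF-------------------WEHMQV-------------------PTAFINSWEHMQVD------------
>Ropefish_alpha
WEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTPPPAY
>Coelacanth_alpha
INSWEHMQVDGLPTAFRSNREHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPPAY
>W.Lungfish_alpha
TAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQPPPAY
>A.Lungfish_alpha
GLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEPPPAY
>Frog_alpha
QVDGLPTAFINSWEHMRVKRLPTAFINSWEHMQVDGLPTAFRVSREHMQVDGLPTAFINSWEHMQVDGLPTAFINPPPAY
>Salamander_alpha
EHMQVDGLPTAFINSWRERRVDGLPTAFINSWEHMQVDGLPRVRRNSWEHMQVDGLPTAFINSWEHMQVDGLPTAPPPAY
>Turtle_alpha
NSWEHMQVDGLPTAFIRSPRHMQVDGLPTAFINSWEHMQVDRHKRAFINSWEHMQVDGLPTAFINSWEHMQVDGLPLPSY
>Chicken_alpha
AFINSWEHMQVDGLPTRTSRSWEHMQVDGLPTAFINSWEHMRQKRLPTAFINSWEHMQVDGLPTAFINSWEHMQVDLPSY
>Cow_alpha
LPTAFINSWEHMQVDGRSRRFINSWEHMQVDGLPTAFINSWRGVRVDGLPTAFINSWEHMQVDGLPTAFINSWEHPPPAY
>Human_alpha
VDGLPTAFINSWEHMQRSRRPTAFINSWEHMQVDGLPTAFIRRARHMQVDGLPTAFINSWEHMQVDGLPTAFINSPPPAY
>Coelacanth_delta
HMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQV------------
>Frog_delta
SWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFIN
>Turtle_delta
FINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTA
>Chicken_delta
PTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGL
>Cow_delta
DGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINRLQRMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQV
>Human_delta
MQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTARLQRWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEH
>S.Lamprey_beta
WEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTPPPHY
>J.Lamprey_beta
INSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGPPPHY
>E.Shark_beta
TAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQPPPRY
>Ropefish_beta
GLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEPPPHY
>Coelacanth_beta
QVDGLPTAFINSWEHMKRERLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINPPPNY
>W.Lungfish_beta
EHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAPPPHY
>A.Lungfish_beta
NSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPPPKY
>Frog_beta
AFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVPPPNY
>Turtle_beta
LPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHPPPNY
>Chicken_beta
VDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSPPPNY
>Cow_beta
HMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFPPPNY
>Human_beta
SWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPPPPNY
>S.Lamprey_gamma
FINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDPPPQY
>J.Lamprey_gamma
PTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMPPPQY
>E.Shark_gamma
DGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINRQHRMQVDGLPTAFINSWEHMQVDGLPTAFINSWPPPNY
>Ropefish_gamma
MQVDGLPTAFINSWEHRKRRGLPTAFINSWEHMQVDGLPTANRKRWEHMQVDGLPTAFINSWEHMQVDGLPTAFIPPPNY
>Coelacanth_gamma
WEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLVKQRINSWEHMQVDGLPTAFINSWEHMQVDGLPTPPPTY
>W.Lungfish_gamma
INSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGPPPQY
>A.Lungfish_gamma
TAFINSWEHMQVDGLPRKLRNSWEHMQVDGLPTAFINSWEHRQYRGLPTAFINSWEHMQVDGLPTAFINSWEHMQPPPQY
>Frog_gamma
GLPTAFINSWEHMQVDRSKRAFINSWEHMQVDGLPTAFINSKRTRQVDGLPTAFINSWEHMQVDGLPTAFINSWEPPPKY
>Turtle_gamma
QVDGLPTAFINSWEHMKVRRLPTAFINSWEHMQVDGLPTAFNKRKEHMQVDGLPTAFINSWEHMQVDGLPTAFINPPPNY
>Chicken_gamma
EHMQVDGLPTAFINSWKVRRVDGLPTAFINSWEHMQVDGLPRKRKNSWEHMQVDGLPTAFINSWEHMQVDGLPTAPPPNY
>Cow_gamma
NSWEHMQVDGLPTAFIRKRRHMQVDGLPTAFINSWEHMQVDRKRKAFINSWEHMQVDGLPTAFINSWEHMQVDGLPPPRY
>Human_gamma
AFINSWEHMQVDGLPTRKRRSWEHMQVDGLPTAFINSWEHMRKRKLPTAFINSWEHMQVDGLPTAFINSWEHMQVPPPKY
>Human_ASIC1
LPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDG
>Coelacanth_ASIC1
VDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQ
>J.Medaka_ASIC1
HMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWE
>Human_ASIC2
SWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFIN
>Coelacanth_ASIC2
FINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQRTKRPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTA
>E.Shark_ASIC1
PTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGL
>J.Medaka_ENaClike1
DGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQV
>J.Medaka_ENaClike2
MQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEH
>Tunicate_ENaClike
WEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINS
>Lancelet_ENaClike
INSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAFINSWEHMQVDGLPTAF
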