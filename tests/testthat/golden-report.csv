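"rater","ac1","pct","wac1","wpct"
"experienced1",0.846563935656185,0.883720930232558,0.94362697519121,0.970930232558139
"experienced2",0.910579202890369,0.931818181818182,0.967530337815677,0.982954545454545
"trained1",0.599975628945396,0.697674418604651,0.784052037916918,0.88953488372093
"trained2",0.815562447735284,0.86046511627907,0.841361011393788,0.918604651162791
"trained3",0.570476605522761,0.674418604651163,0.785925460344065,0.88953488372093
"trained4",0.610575286508567,0.704545454545455,0.769384359400998,0.880681818181818
"rater1",0.493864479338573,0.619047619047619,0.729082501825262,0.863095238095238
"rater2",0.381194514067756,0.534883720930233,0.57256402708272,0.784883720930233
"rater3",0.243206054351565,0.431818181818182,0.535530381050463,0.767045454545455
"rater4",0.27704244637152,0.454545454545455,0.64276048714479,0.818181818181818
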