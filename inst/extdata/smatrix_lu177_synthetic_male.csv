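target,kidneys,liver,lungs,spleen,heart_wall,small_intestine,left_colon,right_colon,rectum,urinary_bladder_wall,salivary_glands,remainder_of_body
kidneys,0.292485,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,0.00115357,7.34806e-05
liver,0.00019867,0.0503724,0.00019867,0.00019867,0.00019867,0.00019867,0.00019867,0.00019867,0.00019867,0.00019867,0.00019867,7.34806e-05
lungs,0.000357606,0.000357606,0.0906704,0.000357606,0.000357606,0.000357606,0.000357606,0.000357606,0.000357606,0.000357606,0.000357606,7.34806e-05
spleen,0.00238404,0.00238404,0.00238404,0.604469,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,7.34806e-05
heart_wall,0.00108365,0.00108365,0.00108365,0.00108365,0.274759,0.00108365,0.00108365,0.00108365,0.00108365,0.00108365,0.00108365,7.34806e-05
small_intestine,0.000558759,0.000558759,0.000558759,0.000558759,0.000558759,0.141672,0.000558759,0.000558759,0.000558759,0.000558759,0.000558759,7.34806e-05
left_colon,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.604469,0.00238404,0.00238404,0.00238404,0.00238404,7.34806e-05
right_colon,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.00238404,0.604469,0.00238404,0.00238404,0.00238404,7.34806e-05
rectum,0.00510865,0.00510865,0.00510865,0.00510865,0.00510865,0.00510865,0.00510865,0.00510865,1.29529,0.00510865,0.00510865,7.34806e-05
urinary_bladder_wall,0.00715212,0.00715212,0.00715212,0.00715212,0.00715212,0.00715212,0.00715212,0.00715212,0.00715212,1.81341,0.00715212,7.34806e-05
salivary_glands,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,0.00420713,1.06671,7.34806e-05
whole_body,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431,0.00125431
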