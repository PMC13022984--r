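network,metric,Adenocarcinoma,High-grade IN,Low-grade IN,Normal,Polyp,Serrated adenoma
TransUnet,dice,0.743,0.824,0.853,0.652,0.781,0.714
SwinUnet,dice,0.774,0.843,0.872,0.683,0.814,0.742
BiSeNet,dice,0.712,0.792,0.834,0.621,0.753,0.683
SegNeXt,dice,0.793,0.861,0.881,0.704,0.832,0.763
SCTNet,dice,0.814,0.873,0.893,0.726,0.854,0.781
MAPSCTNet,dice,0.842,0.901,0.905,0.783,0.882,0.813
TransUnet,jaccard,0.592,0.702,0.743,0.483,0.642,0.554
SwinUnet,jaccard,0.623,0.724,0.773,0.514,0.684,0.592
BiSeNet,jaccard,0.553,0.657,0.714,0.452,0.603,0.517
SegNeXt,jaccard,0.657,0.754,0.803,0.543,0.713,0.617
SCTNet,jaccard,0.684,0.774,0.823,0.567,0.743,0.642
MAPSCTNet,jaccard,0.726,0.824,0.857,0.637,0.786,0.684
TransUnet,asd,9.84,7.21,6.83,12.47,8.93,11.23
SwinUnet,asd,9.13,6.84,6.34,11.83,8.24,10.54
BiSeNet,asd,10.72,8.13,7.52,13.24,9.61,12.14
SegNeXt,asd,8.64,6.25,5.84,10.92,7.83,9.83
SCTNet,asd,8.03,5.92,5.43,10.31,7.14,9.24
MAPSCTNet,asd,6.42,4.37,4.21,8.54,5.68,7.53
TransUnet,precision,0.774,0.842,0.873,0.684,0.813,0.743
SwinUnet,precision,0.793,0.863,0.892,0.713,0.834,0.764
BiSeNet,precision,0.743,0.814,0.854,0.653,0.782,0.713
SegNeXt,precision,0.814,0.863,0.873,0.734,0.853,0.784
SCTNet,precision,0.833,0.894,0.884,0.752,0.872,0.803
MAPSCTNet,precision,0.864,0.913,0.903,0.791,0.904,0.834
TransUnet,recall,0.713,0.803,0.834,0.623,0.752,0.684
SwinUnet,recall,0.754,0.824,0.853,0.654,0.794,0.723
BiSeNet,recall,0.683,0.773,0.814,0.592,0.724,0.653
SegNeXt,recall,0.774,0.843,0.873,0.674,0.813,0.743
SCTNet,recall,0.794,0.894,0.883,0.804,0.834,0.763
MAPSCTNet,recall,0.823,0.884,0.904,0.793,0.863,0.794
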