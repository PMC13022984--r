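network,miou,params_m,flops_g
TransUnet,0.619,105.28,106.35
SwinUnet,0.652,27.17,34.42
BiSeNet,0.583,49.94,55.3
SegNeXt,0.681,27.58,35.25
SCTNet,0.706,18.5,25.0
MAPSCTNet,0.745,21.8,30.7
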