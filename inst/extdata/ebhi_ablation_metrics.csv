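variant,metric,Adenocarcinoma,High-grade IN,Low-grade IN,Normal,Polyp,Serrated adenoma
wo_msaspp,dice,0.798,0.847,0.854,0.724,0.851,0.768
wo_afetam,dice,0.814,0.856,0.868,0.745,0.864,0.785
wo_pdtkd,dice,0.828,0.883,0.877,0.758,0.872,0.796
full,dice,0.842,0.901,0.905,0.783,0.882,0.813
wo_msaspp,jaccard,0.664,0.735,0.792,0.618,0.741,0.623
wo_afetam,jaccard,0.686,0.748,0.812,0.616,0.760,0.656
wo_pdtkd,jaccard,0.702,0.791,0.831,0.623,0.772,0.668
full,jaccard,0.726,0.824,0.857,0.637,0.786,0.684
wo_msaspp,asd,7.85,6.82,4.68,8.24,7.08,8.95
wo_afetam,asd,7.24,6.45,4.42,8.27,6.84,8.42
wo_pdtkd,asd,6.93,5.28,4.45,8.31,6.53,8.05
full,asd,6.42,4.37,4.21,8.54,5.68,7.53
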