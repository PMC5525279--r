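cell_id	TF1	TF2	TF3
c01	0.0075416666666666661	0.0075416666666666661	0.0075416666666666661
c02	0.0059021739130434786	0.0078695652173913049	0.0088532608695652184
c03	0.0071988636363636361	0.0071988636363636361	0.0082272727272727272
c04	0.0079187500000000004	0.0067875000000000001	0.0079187500000000004
c05	0.0069615384615384617	0.0078317307692307696	0.0078317307692307696
c06	0.0082272727272727272	0.0071988636363636361	0.0071988636363636361
c07	0.0086190476190476182	0.0064642857142857141	0.0075416666666666661
c08	0.0069615384615384617	0.0078317307692307696	0.0078317307692307696
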