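phenotype,receptor,lambda_max,relative_density
bird_VS,v,416,1
bird_VS,s,478,2
bird_VS,m,542,2
bird_VS,l,607,4
bird_UVS,u,372,1
bird_UVS,s,456,2
bird_UVS,m,544,2
bird_UVS,l,609,4
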