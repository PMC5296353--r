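scale,fold,rmse
valence,1,0.0800
valence,2,0.0801
valence,3,0.0809
valence,4,0.0816
valence,5,0.0825
tension,1,0.0814
tension,2,0.0813
tension,3,0.0803
tension,4,0.0853
tension,5,0.0822
energy,1,0.0703
energy,2,0.0672
energy,3,0.0672
energy,4,0.0687
energy,5,0.0680
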