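method,scale,metric,value
plsr,valence,r2,0.6617
plsr,tension,r2,0.5605
plsr,energy,r2,0.7535
plsr,valence,q2,0.6032
plsr,tension,q2,0.4406
plsr,energy,q2,0.6867
plsr,valence,rmse,0.0827
plsr,tension,rmse,0.0841
plsr,energy,rmse,0.0772
nn,valence,r2,0.9971
nn,tension,r2,0.9963
nn,energy,r2,0.9983
nn,valence,q2,0.6117
nn,tension,q2,0.4870
nn,energy,q2,0.7658
nn,valence,rmse,0.0810
nn,tension,rmse,0.0821
nn,energy,rmse,0.0683
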