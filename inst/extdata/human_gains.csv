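sim,condition,measure,gain_pct_lo,gain_pct_hi,note
sim2,ecc2,mean_gain,84,84,ground plane; probe 2 deg below FOE; 1 deg/s component
sim2,ecc4,mean_gain,72,72,ground plane; probe 4 deg below FOE; 2 deg/s component
sim1,c1,mean_gain,67,67,frontoparallel; 1 deg/s component (matched to sim2 ecc2)
sim1,c2,mean_gain,50,50,frontoparallel; 2 deg/s component (matched to sim2 ecc4)
sim1,fast_band,gain_band,30,40,frontoparallel; gains approach 0.30-0.40 at the fastest self-motion speeds
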