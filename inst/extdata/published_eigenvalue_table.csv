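pc,eigenvalue,proportion_pct,cumulative_pct
1,8.56e-03,27.9,27.9
2,5.71e-03,18.6,46.5
3,2.77e-03,9.04,55.6
4,2.34e-03,7.64,63.2
5,2.12e-03,6.92,70.1
6,1.67e-03,5.45,75.6
7,1.33e-03,4.35,79.9
8,8.29e-04,2.70,82.6
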