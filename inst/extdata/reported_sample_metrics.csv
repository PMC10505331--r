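sample,sensitivity,specificity,fn_ratio,fp_ratio
1,96.29,73.83,NA,NA
2,93.4,95.8,6.6,4.2
3,95,98.1,5,1.9
4,93,97.6,7,2.4
5,94.6,98.5,5.4,1.5
6,93.3,97.7,6.7,2.3
7,95.2,97.2,4.8,2.8
8,94.5,96.4,5.5,3.6
9,93.6,97.5,6.4,2.5
10,94.5,95.6,5.5,4.4
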