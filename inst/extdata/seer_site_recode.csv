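priority,group,site_low,site_high,hist_low,hist_high
1,Melanoma,C440,C449,8720,8790
2,Breast,C500,C509,8000,9049
3,Uterus,C540,C559,8000,9049
4,Ovary,C569,C569,8000,9049
5,Colon,C180,C189,8000,9049
6,Lung,C340,C349,8000,9049
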