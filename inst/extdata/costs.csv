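parameter,serplulimab,regorafenib
diagnosis,519.26,519.26
drug_per_cycle,3315.68,2149.19
monitor_pfs_y1_3,75.65,113.48
monitor_pfs_y4_5,37.83,37.83
monitor_pfs_gt5,18.91,18.91
monitor_pd,75.65,113.48
subsequent_tx_per_cycle,749.71,1799.71
hosp_pfs,73.38,0.00
hosp_pd,110.08,146.77
admin_pfs,2.97,0.00
admin_pd,1.67,1.80
eol,2046.84,2046.84
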