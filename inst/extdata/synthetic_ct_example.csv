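"sample_id","group","gene","role","ct"
"control_1","control","Tmem119","GOI",25.2056
"control_1","control","Hprt1","reference",20.9153
"control_1","control","Gapdh","reference",19.0545
"control_1","control","Ppia","reference",20.0949
"control_2","control","Tmem119","GOI",25.0606
"control_2","control","Hprt1","reference",20.9841
"control_2","control","Gapdh","reference",19.2267
"control_2","control","Ppia","reference",19.9858
"control_3","control","Tmem119","GOI",25.3028
"control_3","control","Hprt1","reference",20.9906
"control_3","control","Gapdh","reference",19.1957
"control_3","control","Ppia","reference",20.343
"control_4","control","Tmem119","GOI",24.7917
"control_4","control","Hprt1","reference",20.9582
"control_4","control","Gapdh","reference",18.98
"control_4","control","Ppia","reference",20.0954
"treated_1","treated","Tmem119","GOI",22.833
"treated_1","treated","Hprt1","reference",20.6015
"treated_1","treated","Gapdh","reference",18.6339
"treated_1","treated","Ppia","reference",20.198
"treated_2","treated","Tmem119","GOI",22.8297
"treated_2","treated","Hprt1","reference",20.7328
"treated_2","treated","Gapdh","reference",18.9742
"treated_2","treated","Ppia","reference",20.1822
"treated_3","treated","Tmem119","GOI",23.16
"treated_3","treated","Hprt1","reference",20.9354
"treated_3","treated","Gapdh","reference",18.9614
"treated_3","treated","Ppia","reference",19.7355
"treated_4","treated","Tmem119","GOI",22.9447
"treated_4","treated","Hprt1","reference",20.904
"treated_4","treated","Gapdh","reference",19.0683
"treated_4","treated","Ppia","reference",20.1057
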