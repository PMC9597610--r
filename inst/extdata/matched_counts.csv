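comparison,database,outcome,arm,brand,dose,participants,person_years,events
chadox1s_d1_vs_bnt162b2_d1,UK_CPRD,thrombocytopenia,target,ChAdOx1-S,1,1836112,136523,827
chadox1s_d1_vs_bnt162b2_d1,UK_CPRD,thrombocytopenia,comparator,BNT162b2,1,1195498,90381,442
chadox1s_d1_vs_bnt162b2_d1,Germany_DA,thrombocytopenia,target,ChAdOx1-S,1,82281,6234,35
chadox1s_d1_vs_bnt162b2_d1,Germany_DA,thrombocytopenia,comparator,BNT162b2,1,204508,15516,78
chadox1s_d1_vs_bnt162b2_d1,UK_CPRD,arterial_thromboembolism,target,ChAdOx1-S,1,1886308,140256,416
chadox1s_d1_vs_bnt162b2_d1,UK_CPRD,arterial_thromboembolism,comparator,BNT162b2,1,1227495,92807,331
ad26cov2s_vs_bnt162b2_d1,Spain_SIDIAP,thrombocytopenia,target,Ad26.COV2.S,1,106217,5037,49
ad26cov2s_vs_bnt162b2_d1,Spain_SIDIAP,thrombocytopenia,comparator,BNT162b2,1,386334,19944,197
ad26cov2s_vs_bnt162b2_d1,Germany_DA,thrombocytopenia,target,Ad26.COV2.S,1,17933,1213,12
ad26cov2s_vs_bnt162b2_d1,Germany_DA,thrombocytopenia,comparator,BNT162b2,1,65217,4894,14
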