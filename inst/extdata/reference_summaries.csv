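table,metric,median,iqr_low,iqr_high,n,note
manual_inter_ssm,asd_mm,2.6,2.3,3.0,132,
manual_inter_soft_ssm,asd_mm,1.5,1.2,1.8,132,
manual_intra_ssm,asd_mm,2.2,1.9,2.5,18,results-section value
manual_intra_ssm,asd_mm,2.2,1.9,2.6,18,abstract prints a wider upper quartile; discrepancy flagged
manual_intra_soft_ssm,asd_mm,1.0,0.8,1.1,18,
mesh_method_impact_ssm,asd_mm,2.2,1.9,2.5,125,
mesh_method_impact_soft_ssm,asd_mm,0.5,0.4,0.6,125,
semiauto_pairwise,asd_mm,1.4,1.1,1.9,343,
semiauto_pairwise,dice,0.90,0.88,0.92,343,
semiauto_pairwise,hausdorff_mm,5.70,4.47,7.36,343,
semiauto_staple,asd_mm,1.3,1.0,1.7,289,
semiauto_staple,dice,0.91,0.88,0.93,289,
semiauto_staple,hausdorff_mm,5.08,3.94,6.63,289,
semiauto_intra,asd_mm,1.2,0.9,1.7,19,
manual_vs_semiauto_pairwise,asd_mm,1.43,1.20,1.90,315,
manual_vs_consensus,asd_mm,1.38,1.09,1.78,125,
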