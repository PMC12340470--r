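comparison,study,ref_center,ref_iqr_low,ref_iqr_high,ref_n,study_center,study_sd,study_n,report_magnitude
manual_vs_semi_auto,Tutar,1.43,1.20,1.90,315,1.26,0.41,30,FALSE
manual_vs_semi_auto,Gong,1.43,1.20,1.90,315,1.36,0.58,594,FALSE
manual_vs_semi_auto,Shen,1.43,1.20,1.90,315,3.20,0.87,10,FALSE
manual_vs_semi_auto,Pathak,1.43,1.20,1.90,315,4.0,1.5,125,FALSE
inter_manual_soft_ssm,Tutar,1.5,1.2,1.8,132,1.34,0.66,30,FALSE
inter_manual_soft_ssm,Gong,1.5,1.2,1.8,132,1.82,1.44,594,TRUE
inter_manual_soft_ssm,Pathak,1.5,1.2,1.8,132,1.8,1.4,125,FALSE
inter_semi_auto,Pathak,1.4,1.1,1.9,343,0.7,0.4,125,FALSE
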