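variable,site,unit,n_oa,mean_oa,sd_oa,n_healthy,mean_healthy,sd_healthy,d_reported,p_reported,auc_reported
st_rms_ml,tibia,m/s^2,16,1.71,0.45,16,2.00,0.46,0.64,0.08,NA
st_rms_ml,femur,m/s^2,16,1.40,0.45,16,1.42,0.23,0.06,0.83,NA
a_rms,tibia,m/s/deg,16,0.032,0.009,16,0.023,0.005,1.23,0.002,0.81
a_rms,femur,m/s/deg,16,0.044,0.013,16,0.034,0.007,0.97,0.010,0.75
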