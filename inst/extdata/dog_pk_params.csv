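formulation,dose_mg,hl_lambda_z,hl_sd,tmax,tmax_sd,cmax,cmax_sd,auc0t,auc0t_sd,auc0inf,auc0inf_sd,mrt_last,mrt_sd
LEV-IDTs-250,250,3.54,0.32,1.00,0.87,32.01,1.88,176.16,1.09,177.82,0.66,4.68,0.08
LEV-IDTs-500,500,3.36,0.27,1.00,0.87,55.54,4.83,304.95,31.34,307.17,32.22,4.58,0.48
LEV-IDTs-750,750,3.30,0.32,1.67,0.58,82.81,5.14,510.01,10.39,513.44,9.60,4.81,0.43
LEV-IDTs-1000,1000,3.14,0.31,0.83,0.29,118.89,11.07,718.05,93.24,722.43,94.59,5.02,0.40
Spritam-1000,1000,3.13,0.46,0.28,0.21,127.85,7.09,717.68,48.66,721.98,51.03,4.52,0.33
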