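regimen,parameter,observed,predicted
iv_1500,cmax,50.80,54.83
iv_1500,auc0t,367.20,357.40
iv_1500,auc0inf,370.70,358.90
iv_1500,tmax,0.711,0.75
oral_250,cmax,5.51,6.268
oral_250,auc0t,62.56,58.96
oral_250,auc0inf,72.56,59.75
oral_250,tmax,1.67,1.32
oral_500,cmax,12.50,12.54
oral_500,auc0t,138.50,117.90
oral_500,auc0inf,145.40,119.50
oral_500,tmax,0.80,1.32
oral_750,cmax,17.00,18.80
oral_750,auc0t,189.80,176.90
oral_750,auc0inf,196.10,179.30
oral_750,tmax,3.16,1.32
oral_1000,cmax,24.10,25.90
oral_1000,auc0t,222.80,236.60
oral_1000,auc0inf,226.40,239.40
oral_1000,tmax,1.45,1.30
oral_1500,cmax,35.30,35.43
oral_1500,auc0t,402.30,354.70
oral_1500,auc0inf,408.30,356.30
oral_1500,tmax,0.646,1.38
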