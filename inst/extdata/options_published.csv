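regimen_label,category,duration_months,daily_drug_cost,drug_cost,monitoring_cost,total_cost,weight
R-E-CLAM,macrolide_susceptible,14,5.91,2482.2,2162.47,4644.67,0.105
R-E-CLAM,macrolide_susceptible,18,5.91,3191.4,2895.75,6087.15,0.105
RBT-E-CLAM,macrolide_susceptible,14,14.08,5913.6,2162.47,8076.07,0.105
RBT-E-CLAM,macrolide_susceptible,18,14.08,7603.2,2895.75,10498.95,0.105
R-E-AZM,macrolide_susceptible,14,7.42,3116.4,2162.47,5287.87,0.105
R-E-AZM,macrolide_susceptible,18,7.42,4006.8,2895.75,6902.55,0.105
RBT-E-AZM,macrolide_susceptible,14,19.54,8206.8,2162.47,10369.27,0.105
RBT-E-AZM,macrolide_susceptible,18,19.54,10551.6,2895.75,13447.35,0.105
R-E-CLO-AMK,macrolide_resistant,14,5.96,6787.2,2263.3,9050.5,0.0133333333333333
R-E-CLO-AMK,macrolide_resistant,18,5.96,7502.4,2996.58,10498.98,0.0133333333333333
R-E-MOX-AMK,macrolide_resistant,14,7.93,7614.6,2263.3,9877.9,0.0133333333333333
R-E-MOX-AMK,macrolide_resistant,18,7.93,8556.2,2996.58,11552.78,0.0133333333333333
R-E-CLAM-AMX,severe,14,5.91,6766.2,2263.3,9029.5,0.0133333333333333
R-E-CLAM-AMX,severe,18,5.91,7475.4,2996.58,10471.98,0.0133333333333333
RBT-E-CLAM-AMX,severe,14,14.08,10197.6,2263.3,12460.9,0.0133333333333333
RBT-E-CLAM-AMX,severe,18,14.08,11887.2,2996.58,14883.78,0.0133333333333333
R-E-ATZ-AMX,severe,14,7.42,7400.4,2263.3,9663.7,0.0133333333333333
R-E-ATZ-AMX,severe,18,7.42,8290.8,2996.58,11287.38,0.0133333333333333
RBT-E-ATM-AMX,severe,14,19.54,12490.8,2263.3,14754.1,0.0133333333333333
RBT-E-ATM-AMX,severe,18,19.54,12840.2,2996.58,15806.78,0.0133333333333333
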