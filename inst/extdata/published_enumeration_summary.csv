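protocol,classification,positive_samples,n_samples,mean_events_per_ml,se_events_per_ml,pct_of_total,median_events_per_ml,min_events_per_ml,max_events_per_ml
Landscape,DAPI only,15,18,13.69,2.90,3.55,10.84,0.00,51.57
Landscape,CK,7,18,57.00,36.36,14.77,3.55,0.00,549.63
Landscape,Vim,11,18,6.64,1.27,1.72,7.30,0.00,20.16
Landscape,CD45/CD31,10,18,10.29,2.44,2.67,8.05,0.00,33.16
Landscape,CK|Vim,6,18,7.60,1.40,1.97,1.40,0.00,91.29
Landscape,CK|CD45/CD31,4,18,4.66,1.86,1.21,2.13,0.00,30.74
Landscape,Vim|CD45/CD31,11,18,24.52,8.73,6.35,7.79,0.00,121.00
Landscape,CK|Vim|CD45/CD31,15,18,100.40,35.02,26.01,12.89,0.00,453.13
Landscape,Onc CK,12,18,71.59,38.39,18.55,6.64,1.06,657.60
Landscape,Onc CK|Vim,10,18,32.72,13.64,8.48,7.38,0.00,217.65
Landscape,Onc CK|CD45/CD31,0,18,1.47,0.36,0.38,1.12,0.00,4.47
Landscape,Onc CK|Vim|CD45/CD31,14,18,55.37,16.22,14.35,34.32,0.00,268.32
CDX2,DAPI only,18,18,63.72,12.80,8.33,45.29,16.94,226.94
CDX2,CK,12,18,88.14,43.95,11.53,11.97,0.00,597.32
CDX2,CDX2,12,18,11.45,3.28,1.50,7.27,1.04,60.22
CDX2,CD45,3,18,5.44,3.35,0.71,0.00,0.00,59.22
CDX2,CK|CDX2,14,18,19.95,6.71,2.61,11.34,0.00,124.08
CDX2,CK|CD45,12,18,36.66,13.71,4.79,10.02,0.00,203.63
CDX2,CDX2|CD45,12,18,29.37,12.46,3.84,9.80,0.00,185.68
CDX2,CK|CDX2|CD45,14,18,143.67,101.35,18.79,21.79,1.44,1843.34
CDX2,Onc CK,15,18,123.55,60.73,16.16,26.00,2.31,1035.65
CDX2,Onc CK|CDX2,18,18,222.40,65.04,29.08,114.87,15.55,1151.64
CDX2,Onc CK|CD45,0,18,0.06,0.06,0.01,0.00,0.00,1.06
CDX2,Onc CK|CDX2|CD45,10,18,20.27,7.64,2.65,14.50,0.00,1138.28
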