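target,metric,RBNNA,NUBCA,BPNN,IM-RBNNA
nitrogen,MAPE,5.26,8.17,4.82,1.61
nitrogen,MAE,3.097,5.94,3.696,1.403
nitrogen,R2,0.903,0.762,0.877,0.977
phosphorus,MAPE,16.09,19.99,13.36,10.46
phosphorus,MAE,5.061,6.306,4.781,3.641
phosphorus,R2,0.715,0.572,0.702,0.835
potassium,MAPE,11.39,15.56,10.95,8.44
potassium,MAE,21.01,22.54,19.34,18.56
potassium,R2,0.838,0.749,0.875,0.917
yield,MAPE,15.08,16.29,16.44,8.28
yield,MAE,31.56,33.16,32.14,18.56
yield,R2,0.812,0.769,0.767,0.934
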