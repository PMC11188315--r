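plot_id,alk_N,avail_P,avail_K,applied_P,applied_N,applied_K,yield_actual
2-A1,22.74,5.23,64.1,162.61,76.39,167.05,162.65
2-A2,22.53,6.4,60.8,170.53,82.66,180.97,153.81
2-A3,20.78,5.95,66.17,188.64,79.85,171.99,160.81
2-A4,23.52,5.62,74.65,170.2,86.42,177.48,178.93
2-A5,21.89,8.59,77.06,170.52,72.53,184.26,173.38
2-B1,22.68,5.92,58.27,177.08,73.94,179.42,165.55
2-B2,20.01,7.18,63.35,158.52,80.09,174.23,185.35
2-B3,22.36,6.08,85.2,165.77,88,183.21,157.33
2-B4,24.74,5.92,71.92,161.47,75.21,169.92,163.21
2-B5,24.92,7.64,79.59,182.95,84.26,181.62,182.03
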