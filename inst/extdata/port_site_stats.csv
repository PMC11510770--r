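site_id,no_p25,no_median,no_mean,no_p75,no_sd,no2_p25,no2_median,no2_mean,no2_p75,no2_sd
1,9.11,14.47,47.36,29.35,104.41,30.75,40.39,41.86,51.87,16.31
2,50.52,102.24,169.68,193.50,212.35,31.57,48.38,47.13,60.27,20.15
3,30.42,67.13,136.97,148.47,207.79,28.29,45.51,45.21,59.66,23.06
4,32.43,97.95,188.85,233.43,252.61,29.11,47.36,49.77,67.45,28.03
5,36.45,65.26,119.58,127.57,161.76,55.35,75.65,76.84,94.51,28.60
6,31.89,76.51,120.64,165.09,130.24,54.74,78.52,76.56,96.97,31.07
7,23.45,34.17,79.07,74.37,130.56,33.62,42.44,42.88,50.43,12.75
8,98.89,194.97,289.78,367.16,293.95,60.27,79.54,80.30,99.02,28.50
9,18.09,45.29,98.75,116.98,160.07,31.16,42.64,43.05,53.51,17.94
10,28.14,61.51,107.89,124.89,156.11,38.13,58.84,58.54,75.44,27.14
11,69.81,75.98,105.56,96.48,80.39,33.83,53.10,55.05,71.96,27.51
12,90.72,96.08,136.40,119.66,104.10,26.45,34.65,36.31,44.08,13.89
13,38.86,81.07,175.83,216.04,221.01,83.03,122.80,121.08,155.80,51.04
14,39.93,71.42,162.58,168.04,242.09,56.99,81.18,80.29,100.66,31.28
15,99.43,153.83,222.55,266.49,194.26,86.51,119.11,118.79,147.60,41.04
16,76.78,99.83,170.71,196.04,172.43,29.73,56.58,54.93,77.49,30.85
17,71.02,93.00,95.46,106.93,66.49,33.42,52.07,52.74,69.70,26.93
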