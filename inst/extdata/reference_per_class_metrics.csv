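split,class,accuracy,precision,recall,f_score,mcc
TR80,Maize,97.71,95.49,97.37,96.42,94.75
TR80,Banana,97.48,94.21,96.19,95.19,93.49
TR80,Forest,98.08,95.47,94.81,95.14,93.95
TR80,Other,98.39,93.64,92.88,93.26,92.35
TR80,Legume,98.02,86.87,76.79,81.52,80.65
TR80,Structure,99.07,93.03,87.98,90.44,89.99
TS20,Maize,97.44,95.56,97.07,96.30,94.36
TS20,Banana,97.75,94.83,96.30,95.56,94.06
TS20,Forest,98.45,96.72,95.16,95.93,94.98
TS20,Other,98.37,91.73,92.42,92.08,91.17
TS20,Legume,98.06,83.58,80.00,81.75,80.75
TS20,Structure,99.07,95.52,87.67,91.43,91.03
TR70,Maize,97.05,94.53,96.53,95.52,93.34
TR70,Banana,97.54,93.61,96.83,95.19,93.57
TR70,Forest,97.70,94.06,94.28,94.17,92.74
TR70,Other,98.72,95.57,93.41,94.48,93.76
TR70,Legume,98.54,91.52,81.35,86.13,85.53
TR70,Structure,98.27,88.78,76.79,82.35,81.69
TS30,Maize,97.52,95.74,96.37,96.05,94.25
TS30,Banana,97.42,95.25,95.25,95.25,93.47
TS30,Forest,97.57,93.01,94.72,93.86,92.35
TS30,Other,98.55,90.30,97.72,93.86,93.13
TS30,Legume,98.40,92.55,78.38,84.88,84.36
TS30,Structure,98.66,91.46,79.79,85.23,84.74
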