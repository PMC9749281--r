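patient_id,sex,age,height,weight,wbc,neutrophils,lymphocytes,platelets,rbc,hemoglobin,total_protein,cholesterol,crp,glucose,tnm_stage,tumor_type,surgery,radiotherapy,chemotherapy,hypertension,diabetes,smoking,drinking,family_history,os_time,event,ALB
SYN00001,female,56.359,153.545,54.606,7.277,5,1.792,166.768,4.063,128.447,63.997,5.569,3.689,6.757,IV,gastric,1,0,0,1,0,0,0,0,19.484,1,3.52
SYN00002,female,39.331,161.01,68.98,5.924,3.962,1.4,265.205,4.502,109.405,66.646,4.553,2.293,4.843,I,breast,1,0,1,0,0,0,0,1,80.3,0,4.02
SYN00003,female,72.253,163.655,63.19,6.905,5.333,1.097,246.998,3.965,116.11,73.003,4.955,32.521,4.352,II,gastric,1,0,1,0,0,0,0,1,78.041,0,4.37
SYN00004,male,48.213,162.985,61.223,5.944,3.704,1.634,201.581,4.29,158.556,68.423,4.953,12.28,6.08,II,other,0,0,1,0,0,1,0,0,28.716,0,4.12
SYN00005,male,61.053,163.688,55.717,6.473,4.149,1.891,249.311,4.751,157.046,69.03,4.237,1.565,4.987,I,other,1,0,1,0,0,1,0,0,105.892,0,4.33
SYN00006,male,65.192,161.169,62.629,6.997,4.809,1.466,145.593,4.472,131.09,62.718,3.327,4.128,5.054,I,gastric,1,0,1,1,0,0,0,0,41.786,0,3.58
SYN00007,female,59.461,161.008,56.336,5.108,2.693,1.829,382.981,5.089,101.571,69.809,4.099,1.861,6.041,I,colorectal,0,1,0,1,0,0,0,0,39.346,0,4.15
SYN00008,male,74.419,167.912,77.741,8.703,6.467,1.587,136.104,3.99,116.825,73.241,4.66,5.45,7.734,II,breast,0,0,1,0,0,0,0,0,8.644,1,4.23
SYN00009,female,49.956,162.002,61.116,5.034,2.844,1.675,255.817,4.219,111.225,74.138,4.731,8.491,5.532,II,lung,1,0,0,1,0,0,0,0,29.526,1,4.51
SYN00010,male,64.344,165.734,55.669,3.909,2.186,1.275,223.69,4.864,108.533,60.168,3.441,6.992,6.351,I,colorectal,0,0,0,0,0,0,0,0,118.869,0,3.46
SYN00011,male,48.505,168.806,76.552,6.09,3.309,1.928,172.544,3.907,144.835,62.266,4.571,7.159,3.955,II,other,1,0,0,1,0,1,0,0,25.35,1,3.47
SYN00012,female,83.088,154.755,50.271,5.079,3.884,0.771,260.518,3.73,130.681,59.334,3.631,7.206,5.629,I,colorectal,1,0,1,0,1,0,0,0,69.985,0,3.59
SYN00013,male,67.068,177.026,56.614,5.135,2.974,1.728,216.595,4.552,147.787,63.318,5.215,2.17,4.277,IV,gastric,0,0,1,0,0,0,0,0,62.242,1,3.59
SYN00014,male,55.571,183.732,61.671,4.979,3.225,1.306,388.188,3.85,101.816,61.3,4.447,10.903,4.568,III,lung,1,1,0,0,0,0,0,0,16.38,1,3.72
SYN00015,male,68.155,163.587,57.8,6.539,3.316,2.273,192.926,3.739,110.202,62.321,4.04,3.169,7.102,IV,gastric,0,0,1,1,0,1,1,0,66.246,1,3.85
SYN00016,male,46.515,181.437,68.121,7.403,5.407,1.463,345.558,3.836,134.319,74.701,5.039,12.629,6.281,IV,lung,1,0,1,0,0,0,0,0,34.973,1,4.38
SYN00017,female,76.224,153.808,56.414,4.215,1.814,1.634,264.887,4.72,147.986,70.026,3.92,10.15,5.914,I,liver,0,0,0,0,0,0,0,0,100.208,1,4.26
SYN00018,female,46.516,153.756,49.26,4.359,2.184,1.77,196.123,3.842,120.52,63.864,5.447,2.291,5.322,III,other,1,1,1,0,0,0,1,1,46.743,0,3.59
SYN00019,male,42.042,175.382,53.669,4.746,2.447,1.815,227.026,4.298,117.263,74.774,3.942,4.558,4.561,II,gastric,0,0,1,0,0,1,1,0,7.958,1,4.52
SYN00020,female,58.784,156.589,52.438,7.039,5.075,1.44,191.854,3.968,152.759,68.789,3.037,7.998,5.937,II,esophageal,0,0,1,0,0,0,0,0,30.803,1,4.22
SYN00021,male,68.869,172.813,82.529,6.565,4.204,1.69,135.47,4.666,158.062,73.063,3.943,1.482,4.492,I,gastric,1,1,0,1,1,1,0,0,47.349,0,4.57
SYN00022,female,59.276,162.632,52.288,5.131,3.431,1.198,429.602,3.732,132.247,64.25,4.067,8.571,8.505,III,other,1,0,0,0,0,0,0,0,51.559,1,3.8
SYN00023,male,50.923,169.008,58.35,5.544,3.833,1.034,361.869,4.42,137.749,65.378,4.393,2.287,5.683,II,gastric,1,0,1,0,0,1,0,0,34.137,0,3.84
SYN00024,male,72.51,173.313,61.316,7.624,5.483,1.573,280.565,3.734,101.361,59.887,3.658,78.547,6.264,III,gastric,1,1,1,1,0,1,0,1,43.484,0,3.5
SYN00025,male,86.321,176.2,81.493,6.155,4.378,1.197,171.503,4.981,100.715,72.661,4.208,4.943,4.434,III,liver,0,0,0,0,0,0,0,0,72.35,0,4.23
SYN00026,male,37.563,169.723,55.314,6.986,4.773,1.173,289.531,4.287,150.677,61.033,4.694,31.704,6.222,IV,gastric,1,1,0,0,0,1,0,0,51.135,0,3.12
SYN00027,male,75.831,185.832,78.83,6.59,4.774,1.367,210.399,3.224,121.367,59.928,4.569,11.592,7.058,IV,lung,1,0,1,0,1,1,0,0,5.469,0,3.43
SYN00028,male,54.105,173.534,62.77,5.978,3.879,1.362,272.673,4.903,120.447,71.815,4.717,11.992,5.746,I,lung,1,0,0,1,0,1,1,0,36.804,0,3.85
SYN00029,male,70.34,168.786,59.848,4.586,2.491,1.33,306.224,4.187,146.145,63.212,3.749,11.156,5.692,I,esophageal,0,0,1,0,0,0,1,1,95.828,1,3.6
SYN00030,female,39.058,159.41,54.104,10.011,6.861,2.243,250.901,4.391,121.297,64.913,4.767,4.634,7.013,III,breast,1,0,1,0,0,0,1,0,9.948,1,3.78
SYN00031,male,56.494,169.398,68.155,5.431,3.707,1.118,245.089,4.74,119.192,62.671,5.696,23.542,6.331,II,esophageal,0,0,0,1,0,0,1,0,54.681,1,3.92
SYN00032,male,48.709,163.44,62.583,6.331,4.456,1.282,322.965,4.376,131.983,66.659,3.837,4.785,6.212,IV,esophageal,1,0,1,0,0,0,0,0,54.605,0,3.86
SYN00033,male,53.933,173.019,71.528,5.248,2.86,1.813,343.335,5.064,101.818,57.395,6.031,10.965,6.881,IV,lung,0,0,1,0,0,1,0,0,68.388,0,3.21
SYN00034,female,47.388,168.01,68.533,5.473,3.625,1.167,282.027,3.925,116.872,68.016,5.204,9.772,6.047,IV,lung,0,0,0,0,0,0,0,0,66.391,0,3.9
SYN00035,male,63.519,172.297,84.126,6.266,4.232,1.373,222.441,4.559,119.696,72.287,3.595,2.363,8.665,I,esophageal,1,0,1,1,0,0,0,0,74.162,0,4.37
SYN00036,male,72.961,172.229,64.382,6.107,4.218,1.383,320.48,4.328,138.781,69.256,3.657,8.42,6.05,IV,other,0,0,1,0,0,1,0,0,98.479,1,3.87
SYN00037,male,53.894,170.943,46.981,6.28,3.676,1.886,242.265,4.723,137.371,69.1,4.404,2.306,6.367,I,other,1,0,1,1,0,1,0,1,66.81,1,4.31
SYN00038,male,56.86,175.088,61.184,4.492,2.792,1.042,368.9,4.435,118.466,63.273,4.442,5.092,6.638,IV,lung,0,0,1,0,0,0,1,0,3.525,1,4.03
SYN00039,male,47.005,162.3,51.957,6.495,4.527,1.289,180.657,4.409,142.53,65.325,3.731,18.906,6.323,III,breast,0,0,0,0,0,0,0,0,17.179,1,3.62
SYN00040,male,70.504,176.95,68.591,5.728,2.912,1.536,225.473,3.911,132.539,69.593,4.11,1.228,6.348,II,colorectal,1,0,0,0,0,0,1,0,55.516,1,4.03
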