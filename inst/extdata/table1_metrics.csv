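species,common_name,n_t1,n_t2,range_shift,threshold_criterion,algorithm,auc_static,auc_static_sd,auc_dynamic,auc_dynamic_sd,tss,tss_sd,sens_dynamic,sens_dynamic_sd,spec_dynamic,spec_dynamic_sd,sens_static,sens_static_sd,spec_static,spec_static_sd,sens_hybrid,sens_hybrid_sd,spec_hybrid,spec_hybrid_sd
Meleagris gallopavo,Wild turkey,73,967,North,Prevalence,rf,0.577,0.030,0.613,0.032,0.159,0.051,0.425,0.043,0.734,0.036,0.295,0.028,0.844,0.033,0.591,0.041,0.610,0.044
Meleagris gallopavo,Wild turkey,73,967,North,Prevalence,maxent,0.650,0.029,0.652,0.032,0.091,0.047,0.957,0.022,0.134,0.056,0.904,0.034,0.204,0.051,0.995,0.007,0.031,0.020
Centrocercus urophasianus,Greater sage grouse,20,60,South,Prevalence,rf,0.943,0.020,0.927,0.021,0.721,0.060,0.951,0.055,0.768,0.033,0.955,0.054,0.794,0.033,0.997,0.016,0.591,0.041
Centrocercus urophasianus,Greater sage grouse,20,60,South,Prevalence,maxent,0.951,0.016,0.944,0.015,0.652,0.047,0.999,0.007,0.653,0.048,0.993,0.020,0.610,0.058,0.999,0.001,0.398,0.067
Tympanuchus cupido,Greater prairie chicken,19,35,North,Prevalence,rf,0.827,0.077,0.838,0.067,0.479,0.158,0.749,0.153,0.745,0.038,0.751,0.140,0.779,0.030,0.934,0.093,0.577,0.042
Tympanuchus cupido,Greater prairie chicken,19,35,North,Prevalence,maxent,0.875,0.041,0.910,0.032,0.095,0.091,0.999,0.001,0.095,0.091,0.999,0.001,0.082,0.071,0.999,0.001,0.013,0.021
Callipepla gambelii,Gambel's quail,27,78,North,Prevalence,rf,0.943,0.021,0.938,0.021,0.723,0.058,0.953,0.051,0.768,0.033,0.919,0.059,0.836,0.026,0.996,0.013,0.625,0.043
Callipepla gambelii,Gambel's quail,27,78,North,Prevalence,maxent,0.955,0.015,0.948,0.013,0.669,0.034,0.999,0.001,0.670,0.034,0.997,0.018,0.710,0.038,0.999,0.001,0.463,0.039
Melanerpes erythrocephalus,Red-headed woodpecker,624,852,South,Maximum kappa,rf,0.834,0.015,0.814,0.018,0.402,0.041,0.929,0.017,0.472,0.038,0.910,0.016,0.581,0.030,0.994,0.005,0.215,0.029
Melanerpes erythrocephalus,Red-headed woodpecker,624,852,South,Maximum kappa,maxent,0.877,0.016,0.870,0.016,0.613,0.035,0.905,0.019,0.709,0.032,0.877,0.021,0.743,0.029,0.987,0.007,0.420,0.031
Melanerpes carolinus,Red-bellied woodpecker,599,830,North,Maximum kappa,rf,0.776,0.020,0.766,0.019,0.311,0.037,0.912,0.017,0.398,0.033,0.754,0.028,0.579,0.031,0.977,0.009,0.201,0.026
Melanerpes carolinus,Red-bellied woodpecker,599,830,North,Maximum kappa,maxent,0.852,0.017,0.806,0.019,0.466,0.036,0.852,0.022,0.614,0.029,0.748,0.030,0.768,0.026,0.962,0.012,0.397,0.031
Corvus ossifragus,Fish crow,153,404,North,Prevalence,rf,0.933,0.014,0.912,0.015,0.605,0.051,0.755,0.050,0.851,0.022,0.736,0.044,0.931,0.016,0.938,0.025,0.741,0.026
Corvus ossifragus,Fish crow,153,404,North,Prevalence,maxent,0.938,0.012,0.921,0.013,0.702,0.034,0.919,0.027,0.783,0.026,0.879,0.031,0.849,0.021,0.989,0.011,0.605,0.033
Poecile carolinensis,Carolina chickadee,468,791,North,Maximum kappa,rf,0.911,0.013,0.914,0.011,0.686,0.030,0.956,0.016,0.730,0.024,0.474,0.034,0.974,0.009,0.980,0.011,0.662,0.029
Poecile carolinensis,Carolina chickadee,468,791,North,Maximum kappa,maxent,0.935,0.011,0.877,0.015,0.674,0.029,0.957,0.015,0.716,0.027,0.499,0.043,0.966,0.011,0.978,0.011,0.653,0.030
Thryothorus ludovicianus,Carolina wren,535,689,North,Maximum kappa,rf,0.815,0.018,0.868,0.014,0.451,0.030,0.991,0.007,0.459,0.030,0.828,0.023,0.602,0.025,0.999,0.002,0.248,0.022
Thryothorus ludovicianus,Carolina wren,535,689,North,Maximum kappa,maxent,0.861,0.017,0.875,0.018,0.662,0.032,0.960,0.017,0.702,0.028,0.847,0.023,0.766,0.027,0.994,0.006,0.454,0.032
Thryomanes bewickii,Bewick's wren,246,440,South,Prevalence,rf,0.780,0.024,0.725,0.023,0.332,0.041,0.824,0.030,0.507,0.031,0.783,0.034,0.658,0.032,0.961,0.020,0.307,0.032
Thryomanes bewickii,Bewick's wren,246,440,South,Prevalence,maxent,0.774,0.024,0.717,0.024,0.335,0.044,0.881,0.028,0.454,0.041,0.829,0.037,0.611,0.033,0.982,0.012,0.249,0.033
Aimophila aestivalis,Bachman's sparrow,81,95,South,Prevalence,rf,0.962,0.012,0.954,0.015,0.762,0.041,0.976,0.035,0.785,0.026,0.955,0.042,0.859,0.021,0.999,0.004,0.657,0.031
Aimophila aestivalis,Bachman's sparrow,81,95,South,Prevalence,maxent,0.965,0.010,0.957,0.013,0.716,0.031,0.999,0.004,0.716,0.031,0.986,0.021,0.772,0.028,0.999,0.001,0.536,0.037
Agelaius tricolor,Tricolored blackbird,15,29,North,Prevalence,rf,0.942,0.044,0.901,0.054,0.654,0.127,0.866,0.113,0.786,0.043,0.919,0.098,0.833,0.035,0.984,0.049,0.659,0.052
Agelaius tricolor,Tricolored blackbird,15,29,North,Prevalence,maxent,0.954,0.019,0.940,0.030,0.670,0.065,0.976,0.079,0.694,0.069,0.983,0.065,0.727,0.064,0.997,0.020,0.515,0.121
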