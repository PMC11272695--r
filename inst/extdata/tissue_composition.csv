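tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,alb_ratio,lip_ratio,f_protein
adipose,0.135,0.017,0.790,0.0016,0.40,0.049,0.068,0.020
bone,0.100,0.346,0.017,0.0017,0.67,0.100,0.050,0.200
brain,0.162,0.620,0.051,0.0565,0.40,0.048,0.041,0.080
gut,0.282,0.475,0.049,0.0163,2.41,0.158,0.0141,0.150
heart,0.320,0.456,0.012,0.0166,2.25,0.157,0.0160,0.160
kidney,0.273,0.483,0.021,0.0162,5.03,0.130,0.0137,0.160
liver,0.161,0.573,0.035,0.0252,4.56,0.086,0.0161,0.180
lung,0.336,0.446,0.003,0.0090,3.91,0.212,0.0168,0.150
muscle,0.118,0.630,0.024,0.0072,1.53,0.064,0.0059,0.190
skin,0.382,0.291,0.028,0.0111,1.32,0.277,0.0096,0.250
spleen,0.207,0.579,0.020,0.0198,3.18,0.097,0.0207,0.150
rest,0.200,0.520,0.040,0.0120,2.00,0.100,0.0150,0.170
plasma,0.945,0.000,0.0023,0.0013,0.04,1.000,1.0000,0.050
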