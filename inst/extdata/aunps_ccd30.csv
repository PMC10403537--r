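std,run,type,X1,X2,X3,X4,temperature_C,time_d,haucl4_ug_ml,ph,response,ref_pred_ccd,ref_resid_ccd,ref_pred_ann,ref_resid_ann
2,1,factorial,1,-1,-1,-1,40,3,400,5,356.17,328.06,28.11,360.58,4.41
22,2,axial,0,0,2,0,35,4,1000,6,866.29,845.4,20.88,870.36,4.07
15,3,factorial,-1,1,1,1,30,5,800,7,604.77,609.52,-4.75,605.58,0.81
27,4,center,0,0,0,0,35,4,600,6,559.57,575.71,-16.14,576.26,16.69
3,5,factorial,-1,1,-1,-1,30,5,400,5,272.23,247.95,24.28,268.04,-4.19
26,6,center,0,0,0,0,35,4,600,6,588.63,575.71,12.91,576.26,-12.37
13,7,factorial,-1,-1,1,1,30,3,800,7,709.33,715.06,-5.73,709.66,0.33
16,8,factorial,1,1,1,1,40,5,800,7,717.77,732.56,-14.78,716.99,-0.78
17,9,axial,-2,0,0,0,25,4,600,6,540.2,528.51,11.69,540.75,0.55
8,10,factorial,1,1,1,-1,40,5,800,5,556.34,551.85,4.5,556.66,0.32
6,11,factorial,1,-1,1,-1,40,3,800,5,756.36,734.86,21.49,755.98,-0.38
1,12,factorial,-1,-1,-1,-1,30,3,400,5,382,371.1,10.9,381.04,-0.96
9,13,factorial,-1,-1,-1,1,30,3,400,7,398.72,379.85,18.87,397.25,-1.47
12,14,factorial,1,1,-1,1,40,5,400,7,385.23,355.71,29.51,384.85,-0.38
4,15,factorial,1,1,-1,-1,40,5,400,5,278.68,276.84,1.85,256.93,-21.75
30,16,center,0,0,0,0,35,4,600,6,556.34,575.71,-19.37,576.26,19.92
24,17,axial,0,0,0,2,35,4,600,8,378.77,373.48,5.29,380.08,1.31
18,18,axial,2,0,0,0,45,4,600,6,577.35,608.52,-31.17,583.7,6.35
21,19,axial,0,0,-2,0,35,4,200,6,194.83,235.19,-40.37,195.48,0.65
10,20,factorial,1,-1,-1,1,40,3,400,7,269.59,257.52,12.06,269.06,-0.53
25,21,center,0,0,0,0,35,4,600,6,588.63,575.71,12.91,576.26,-12.37
5,22,factorial,-1,-1,1,-1,30,3,800,5,598.31,604.46,-6.15,598.54,0.23
11,23,factorial,-1,1,-1,1,30,5,400,7,380.74,406.11,-25.37,381.75,1.01
19,24,axial,0,-2,0,0,35,2,600,6,583.02,612.6,-29.58,585.24,2.22
14,25,factorial,1,-1,1,1,40,3,800,7,765.25,766.16,-0.9172,761.2,-4.05
28,26,center,0,0,0,0,35,4,600,6,572.48,575.71,-3.23,576.26,3.78
7,27,factorial,-1,1,1,-1,30,5,800,5,333.57,349.51,-15.94,335.31,1.74
20,28,axial,0,2,0,0,35,6,600,6,465.94,455.85,10.1,467.1,1.16
29,29,center,0,0,0,0,35,4,600,6,588.63,575.71,12.91,576.26,-12.37
23,30,axial,0,0,0,-2,35,4,600,4,159.23,184.01,-24.78,160.23,1
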