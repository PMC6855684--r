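id,group,age_yr,gender,crps_duration_yr,pain_scan,pain_2d,pain_7d,ppt_left,ppt_right,laterality,disability_score
C1,control,38.5,F,,1,0,0,50.5,62.2,87.5,
C2,control,42.8,M,,4,0,0,13.4,13.6,87.5,
C3,control,52.8,M,,0,0,0,43.7,40.8,87.5,
C4,control,41.1,M,,0,0,0,4.72,3.87,100,
C5,control,56.6,M,,0,1,1,5.03,4.83,73.3,
C6,control,42.3,M,,0,0,0,3.6,4.78,87.5,
C7,control,34.1,M,,0,0,0,3.84,4.72,64.7,
C8,control,53.0,M,,0,0,0,5.36,5.55,66.7,
C9,control,48.7,F,,0,0,0,7.92,7.39,100,
C10,control,56.5,M,,0,0,0,3.92,3.27,83.3,
C11,control,46.9,M,,0,0,0,5.58,5.73,100,
C12,control,38.4,M,,0,0,0,3.7,4.75,100,
C13,control,47.8,M,,0,0,0,5.6,5.53,-100,
C14,control,25.2,F,,0,0,0,4.41,4.88,100,
C15,control,19.9,M,,0,0,0,5.4,5.14,12.5,
C16,control,49.2,M,,0,0,0,6.52,7.71,100,
C17,control,69.4,M,,0,0,0,3.83,3.42,100,
P1,left-CRPS,42.4,M,1.2,7,7,8,1.9,12.2,50,
P2,left-CRPS,42.8,M,0.9,8,4,4,10.6,12.3,83.3,
P3,left-CRPS,55.6,M,0.5,9,8,9,2.06,4.13,83.3,
P4,left-CRPS,45.3,M,3.8,7,8,8,1.8,2.55,4.3,
P5,left-CRPS,66.7,M,0.4,2,9,7,0.88,4.31,73.9,
P6,left-CRPS,47.8,M,4.1,0,3,5,2.9,3.89,100,
P7,left-CRPS,41.9,M,14.9,7,6,6,0.33,3.55,100,
P8,left-CRPS,29.2,M,1.8,6,7,5,0.76,2.06,-100,
P9,right-CRPS,53.4,M,4.5,9,6,7,49.2,15.5,100,
P10,right-CRPS,38.1,M,0.4,8,6,5,6.925,2.925,85.7,
P11,right-CRPS,51.6,M,0.4,2,3,3,4.77,3.53,89.5,
P12,right-CRPS,34.7,M,2.9,7,6,6,3.82,1.3,73.3,
P13,right-CRPS,48.7,F,2.6,8,7,7,12.59,4.94,100,
P14,right-CRPS,46.7,M,7.5,5,3,3,2.37,1.06,66.7,
P15,right-CRPS,56.8,M,14.6,10,3,3,3.07,0.9,100,
P16,right-CRPS,26.6,M,1.9,7,6,3,3.1,0.98,-66.7,
P17,right-CRPS,21.4,F,2.6,0,4,5,4.79,3.84,100,
P18,right-CRPS,44.9,M,18.3,9,8,8,3.63,2.45,64.7,
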