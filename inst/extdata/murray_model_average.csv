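term,label,estimate,lower_ci,upper_ci,relative_importance
intercept,Intercept,1.8232,0.4201,3.2264,NA
capture_murray,Tagged in Murray River,2.9833,1.8063,4.1603,100.0
mean_flow:capture_murray,Mean weekly flow : tagged in Murray River,0.0000,-0.0001,0.0000,49.0
cv_flow:capture_murray,Mean weekly flow CV : tagged in Murray River,-0.0007,-0.0025,0.0011,23.8
pct_change_flow:capture_murray,Percentage change in flow : tagged in Murray River,0.7635,-5.0526,6.5797,15.5
mean_temp:capture_murray,Mean weekly temperature : tagged in Murray River,0.0442,-0.0495,0.1379,38.3
mean_temp:capture_murray:spawning,Mean weekly temperature : tagged in Murray River : spawning season,-0.1229,-0.3663,0.1205,5.4
cv_temp:capture_murray,Mean weekly temperature CV : tagged in Murray River,-4.0046,-24.3235,16.3144,16.4
pct_change_temp:capture_murray,Percentage change in temperature : tagged in Murray River,-3.3183,-22.8978,16.2612,21.7
capture_murray:spawning,Tagged in Murray River : spawning season,0.1737,-1.3181,1.6655,34.2
mean_flow,Mean weekly flow,0.0000,0.0000,0.0001,85.2
mean_flow:spawning,Mean weekly flow : spawning season,0.0000,-0.0001,0.0000,27.9
cv_flow,Mean weekly flow CV,-0.0003,-0.0015,0.0009,77.2
cv_flow:spawning,Mean weekly flow CV : spawning season,0.0006,-0.0026,0.0037,21.3
pct_change_flow,Percentage change in flow,-1.6685,-5.0712,1.7341,57.1
pct_change_flow:spawning,Percentage change in flow : spawning season,3.0913,-2.8064,8.9889,18.0
mean_temp,Mean weekly temperature,0.0405,-0.0409,0.1220,99.6
mean_temp:spawning,Mean weekly temperature : spawning season,-0.1897,-0.3020,-0.0774,96.9
cv_temp,Mean weekly temperature CV,-10.0179,-22.0643,2.0284,50.1
cv_temp:spawning,Mean weekly temperature CV : spawning season,11.3274,-12.7419,35.3968,19.4
pct_change_temp,Percentage change in temperature,9.4279,-5.2439,24.0996,65.8
pct_change_temp:spawning,Percentage change in temperature : spawning season,-12.0243,-35.0409,10.9923,30.8
spawning,Spawning season,2.8650,0.6558,5.0742,99.9
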