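item_id,raw_score,t_score,se,n
nrs_fatigue,0,37.6,6.3,197
nrs_fatigue,1,44.7,4.8,247
nrs_fatigue,2,48.2,4.6,210
nrs_fatigue,3,50.9,4.6,226
nrs_fatigue,4,53.1,4.6,146
nrs_fatigue,5,55.3,4.7,235
nrs_fatigue,6,57.8,4.7,166
nrs_fatigue,7,60.5,4.9,188
nrs_fatigue,8,64.3,5.2,112
nrs_fatigue,9,68.0,5.5,29
nrs_fatigue,10,72.2,6.4,17
nrs_pain_intensity,0,37.8,6.4,579
nrs_pain_intensity,1,45.7,5.0,258
nrs_pain_intensity,2,50.4,4.8,223
nrs_pain_intensity,3,54.1,4.8,185
nrs_pain_intensity,4,56.9,4.8,105
nrs_pain_intensity,5,59.3,4.9,134
nrs_pain_intensity,6,62.2,5.1,109
nrs_pain_intensity,7,64.9,5.3,83
nrs_pain_intensity,8,68.1,5.7,66
nrs_pain_intensity,9,71.4,6.1,23
nrs_pain_intensity,10,74.9,6.8,17
nrs_sleep_disturbance,0,35.0,6.9,174
nrs_sleep_disturbance,1,41.0,5.8,228
nrs_sleep_disturbance,2,45.5,5.6,316
nrs_sleep_disturbance,3,49.4,5.4,276
nrs_sleep_disturbance,4,52.3,5.4,193
nrs_sleep_disturbance,5,55.0,5.5,224
nrs_sleep_disturbance,6,57.6,5.6,127
nrs_sleep_disturbance,7,60.3,5.8,122
nrs_sleep_disturbance,8,63.6,6.2,76
nrs_sleep_disturbance,9,66.7,6.5,23
nrs_sleep_disturbance,10,70.1,7.4,20
nrs_anxiety,0,39.9,6.8,500
nrs_anxiety,1,47.4,5.1,300
nrs_anxiety,2,50.9,5.0,245
nrs_anxiety,3,53.6,5.0,173
nrs_anxiety,4,55.6,5.1,117
nrs_anxiety,5,57.4,5.1,135
nrs_anxiety,6,59.4,5.2,104
nrs_anxiety,7,61.6,5.4,91
nrs_anxiety,8,64.1,5.6,66
nrs_anxiety,9,67.4,6.1,35
nrs_anxiety,10,71.9,7.0,10
nrs_depression,0,41.5,6.7,860
nrs_depression,1,49.9,4.3,295
nrs_depression,2,52.9,4.3,185
nrs_depression,3,55.4,4.3,140
nrs_depression,4,57.4,4.3,79
nrs_depression,5,59.4,4.4,80
nrs_depression,6,61.3,4.4,38
nrs_depression,7,63.3,4.6,50
nrs_depression,8,66.2,4.8,26
nrs_depression,9,69.2,5.0,11
nrs_depression,10,73.5,5.9,8
ctcae_fatigue_severity,1,37.8,6.1,222
ctcae_fatigue_severity,2,47.7,4.8,648
ctcae_fatigue_severity,3,55.8,4.7,628
ctcae_fatigue_severity,4,63.0,4.7,224
ctcae_fatigue_severity,5,70.2,5.7,52
ctcae_fatigue_interference,1,40.0,6.1,402
ctcae_fatigue_interference,2,50.0,4.0,607
ctcae_fatigue_interference,3,56.7,3.8,469
ctcae_fatigue_interference,4,63.1,4.1,244
ctcae_fatigue_interference,5,71.1,4.9,49
ctcae_pain_intensity,1,36.2,5.7,551
ctcae_pain_intensity,2,47.5,5.0,541
ctcae_pain_intensity,3,57.1,4.5,419
ctcae_pain_intensity,4,65.5,4.6,216
ctcae_pain_intensity,5,74.0,5.2,55
ctcae_pain_interference,1,43.3,6.8,844
ctcae_pain_interference,2,54.2,4.0,440
ctcae_pain_interference,3,59.8,3.9,290
ctcae_pain_interference,4,65.2,4.1,156
ctcae_pain_interference,5,71.9,5.1,53
ctcae_sleep_severity,1,39.7,6.5,550
ctcae_sleep_severity,2,48.7,4.8,511
ctcae_sleep_severity,3,55.7,5.0,517
ctcae_sleep_severity,4,63.2,5.2,170
ctcae_sleep_severity,5,70.6,6.0,34
ctcae_sleep_interference,1,42.1,7.1,762
ctcae_sleep_interference,2,51.4,5.4,518
ctcae_sleep_interference,3,57.5,5.5,342
ctcae_sleep_interference,4,63.5,6.0,131
ctcae_sleep_interference,5,70.0,6.9,25
ctcae_anxiety_severity,1,40.7,6.6,570
ctcae_anxiety_severity,2,51.0,4.9,563
ctcae_anxiety_severity,3,58.6,4.9,460
ctcae_anxiety_severity,4,65.5,5.1,162
ctcae_anxiety_severity,5,72.4,5.9,21
ctcae_dep_cheer_frequency,1,43.0,6.9,1065
ctcae_dep_cheer_frequency,2,53.5,4.3,436
ctcae_dep_cheer_frequency,3,59.6,4.5,203
ctcae_dep_cheer_frequency,4,65.4,4.6,53
ctcae_dep_cheer_frequency,5,71.6,5.5,16
ctcae_dep_cheer_severity,1,43.6,6.9,1160
ctcae_dep_cheer_severity,2,54.6,4.0,370
ctcae_dep_cheer_severity,3,60.8,4.2,180
ctcae_dep_cheer_severity,4,67.2,4.2,42
ctcae_dep_cheer_severity,5,73.7,5.1,8
ctcae_dep_cheer_interference,1,44.4,7.2,1248
ctcae_dep_cheer_interference,2,55.8,4.3,342
ctcae_dep_cheer_interference,3,61.5,4.4,122
ctcae_dep_cheer_interference,4,66.7,4.6,42
ctcae_dep_cheer_interference,5,72.8,5.5,11
ctcae_dep_sad_frequency,1,38.4,6.1,509
ctcae_dep_sad_frequency,2,48.4,4.8,729
ctcae_dep_sad_frequency,3,56.3,4.6,397
ctcae_dep_sad_frequency,4,63.7,4.9,116
ctcae_dep_sad_frequency,5,71.8,5.6,14
ctcae_dep_sad_severity,1,39.7,6.3,629
ctcae_dep_sad_severity,2,50.2,5.0,772
ctcae_dep_sad_severity,3,58.5,4.8,299
ctcae_dep_sad_severity,4,65.0,4.7,50
ctcae_dep_sad_severity,5,70.6,5.8,19
ctcae_dep_sad_interference,1,43.5,7.1,1128
ctcae_dep_sad_interference,2,54.3,4.5,422
ctcae_dep_sad_interference,3,60.3,4.5,154
ctcae_dep_sad_interference,4,65.7,4.8,51
ctcae_dep_sad_interference,5,72.0,5.7,13
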