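item_id,scale_id,instrument,role,code_offset,slope,b1,b2,b3,b4,b5,b6,b7,b8,b9,b10,sl_a,sl_b
nrs_anxiety,anxiety,NRS,target,0,2.99,-0.63,-0.08,0.33,0.63,0.85,1.13,1.41,1.73,2.16,2.79,0.96,-0.00
nrs_depression,depression,NRS,target,0,3.75,-0.23,0.20,0.51,0.80,1.01,1.30,1.47,1.82,2.22,2.61,0.90,-0.20
nrs_fatigue,fatigue,NRS,target,0,3.34,-0.97,-0.41,-0.06,0.28,0.50,0.85,1.13,1.59,2.18,2.59,0.84,0.26
nrs_pain_intensity,pain_intensity,NRS,target,0,3.26,-0.94,-0.20,0.32,0.75,1.02,1.40,1.77,2.16,2.71,3.15,1.59,-0.26
nrs_sleep_disturbance,sleep_disturbance,NRS,target,0,2.66,-1.65,-0.98,-0.32,0.16,0.49,0.92,1.25,1.72,2.31,2.70,1.00,-0.05
ctcae_anxiety_severity,anxiety,PRO-CTCAE,target,1,3.68,-0.38,0.65,1.59,2.47,,,,,,,0.96,-0.00
ctcae_anxiety_frequency,anxiety,PRO-CTCAE,target,1,3.95,-0.47,0.39,1.33,2.30,,,,,,,0.96,-0.00
ctcae_anxiety_interference,anxiety,PRO-CTCAE,target,1,3.43,0.34,1.09,1.83,2.56,,,,,,,0.96,-0.00
ctcae_dep_cheer_frequency,depression,PRO-CTCAE,target,1,4.07,0.06,0.81,1.58,2.22,,,,,,,0.90,-0.20
ctcae_dep_sad_frequency,depression,PRO-CTCAE,target,1,3.96,-0.74,0.33,1.26,2.28,,,,,,,0.90,-0.20
ctcae_dep_cheer_interference,depression,PRO-CTCAE,target,1,4.11,0.34,1.08,1.73,2.39,,,,,,,0.90,-0.20
ctcae_dep_sad_interference,depression,PRO-CTCAE,target,1,3.90,0.15,0.94,1.62,2.32,,,,,,,0.90,-0.20
ctcae_dep_cheer_severity,depression,PRO-CTCAE,target,1,4.61,0.20,0.89,1.71,2.40,,,,,,,0.90,-0.20
ctcae_dep_sad_severity,depression,PRO-CTCAE,target,1,3.80,-0.55,0.61,1.61,2.14,,,,,,,0.90,-0.20
ctcae_fatigue_interference,fatigue,PRO-CTCAE,target,1,4.95,-0.42,0.43,1.14,1.99,,,,,,,0.84,0.26
ctcae_fatigue_severity,fatigue,PRO-CTCAE,target,1,3.89,-0.85,0.25,1.24,2.06,,,,,,,0.84,0.26
ctcae_pain_intensity,pain_intensity,PRO-CTCAE,target,1,4.42,-1.02,0.36,1.43,2.47,,,,,,,1.58,-0.26
ctcae_pain_interference,pain_interference,PRO-CTCAE,target,1,4.67,0.14,0.85,1.46,2.14,,,,,,,1.14,0.27
ctcae_sleep_interference,sleep_disturbance,PRO-CTCAE,target,1,2.90,-0.23,0.63,1.49,2.47,,,,,,,1.00,-0.05
ctcae_sleep_severity,sleep_disturbance,PRO-CTCAE,target,1,3.54,-0.58,0.25,1.28,2.23,,,,,,,1.00,-0.05
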