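{
  "heart_rate": 79.9224499629915,
  "t_sas": 0.267110261285494,
  "t_svs": 0.508964854336162,
  "t_pws": 14.7737115584567,
  "E_act_ra": 449.042471715782,
  "K_pas1_ra": 522.420345420626,
  "K_pas2_ra": 0.106428811167307,
  "V0_ra": 41.8673069027608,
  "E_act_rv": 361.541292026903,
  "K_pas1_rv": 236.136066373316,
  "K_pas2_rv": 0.0211831263992226,
  "V0_rv": 2.60797731243856,
  "E_act_la": 586.53152454761,
  "K_pas1_la": 1292.81639614096,
  "K_pas2_la": 0.0808187361211413,
  "V0_la": 23.042933177351,
  "E_act_lv": 1938.59237483316,
  "K_pas1_lv": 1944.96192050768,
  "K_pas2_lv": 0.023543555023714,
  "V0_lv": 7.36764650493513,
  "R_ra_rv": 8.12794405811259,
  "R_rv_pa": 5.88906914473953,
  "R_la_lv": 9.61668654625442,
  "R_lv_ao": 12.8656537242605,
  "L_ra_rv": 0.23395445245044,
  "L_rv_pa": 0.104539312049407,
  "L_la_lv": 0.327195463420041,
  "L_lv_ao": 0.174730257893147,
  "C_ao": 0.000719407515116884,
  "C_sys": 0.030350330889888,
  "R_sys_a": 1608.92601565193,
  "R_sys_v": 214.801898537971,
  "C_pa": 0.00107083702833778,
  "R_pa": 263.359713683101,
  "V_ra_ini": 107.552033277614,
  "V_rv_ini": 254.642925365147,
  "V_la_ini": 163.455984471655,
  "V_lv_ini": 194.600125868163,
  "Q_ra_rv_ini": 110.022244364749,
  "Q_rv_pa_ini": 81.6593763450516,
  "Q_la_lv_ini": 70.3715682728351,
  "Q_lv_ao_ini": 109.81137321094,
  "P_ao_ini": 121827.629555935,
  "P_sys_ini": 24687.834616978,
  "P_pa_ini": 34892.2248562162
}
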