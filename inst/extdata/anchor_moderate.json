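{
  "heart_rate": 80.0123236701361,
  "t_sas": 0.245118516507886,
  "t_svs": 0.512158333908593,
  "t_pws": 13.3971211923948,
  "E_act_ra": 303.193321691289,
  "K_pas1_ra": 391.638549910051,
  "K_pas2_ra": 0.0889511215345956,
  "V0_ra": 25.8439839133971,
  "E_act_rv": 300.633752263439,
  "K_pas1_rv": 231.766729641058,
  "K_pas2_rv": 0.0198412730446418,
  "V0_rv": 6.52160475657168,
  "E_act_la": 315.348986378042,
  "K_pas1_la": 845.965142958908,
  "K_pas2_la": 0.0793937532909139,
  "V0_la": 12.9740283036296,
  "E_act_lv": 2085.29267512214,
  "K_pas1_lv": 1080.67929713319,
  "K_pas2_lv": 0.0249866794756188,
  "V0_lv": 6.08894454654867,
  "R_ra_rv": 8.12794405811259,
  "R_rv_pa": 5.88906914473953,
  "R_la_lv": 9.61668654625442,
  "R_lv_ao": 12.8656537242605,
  "L_ra_rv": 0.23395445245044,
  "L_rv_pa": 0.104539312049407,
  "L_la_lv": 0.327195463420041,
  "L_lv_ao": 0.174730257893147,
  "C_ao": 0.000892569441706377,
  "C_sys": 0.0278195115654018,
  "R_sys_a": 1404.47556503542,
  "R_sys_v": 206.364416498952,
  "C_pa": 0.00333900558327096,
  "R_pa": 185.191176852992,
  "V_ra_ini": 75.4444297426997,
  "V_rv_ini": 210.26407959781,
  "V_la_ini": 103.925760329841,
  "V_lv_ini": 193.424622129058,
  "Q_ra_rv_ini": 112.243451954148,
  "Q_rv_pa_ini": 44.7565931600933,
  "Q_la_lv_ini": 49.1655813358152,
  "Q_lv_ao_ini": 58.6477467816932,
  "P_ao_ini": 124152.446241824,
  "P_sys_ini": 21690.8846747203,
  "P_pa_ini": 31219.6663070357
}
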