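{
  "heart_rate": 80.1021973772808,
  "t_sas": 0.223126771730278,
  "t_svs": 0.515351813481024,
  "t_pws": 12.0205308263329,
  "E_act_ra": 157.344171666795,
  "K_pas1_ra": 260.856754399477,
  "K_pas2_ra": 0.0714734319018842,
  "V0_ra": 9.82066092403333,
  "E_act_rv": 239.726212499975,
  "K_pas1_rv": 227.3973929088,
  "K_pas2_rv": 0.018499419690061,
  "V0_rv": 10.4352322007048,
  "E_act_la": 44.1664482084748,
  "K_pas1_la": 399.113889776856,
  "K_pas2_la": 0.0779687704606865,
  "V0_la": 2.90512342990824,
  "E_act_lv": 2231.99297541112,
  "K_pas1_lv": 216.396673758702,
  "K_pas2_lv": 0.0264298039275237,
  "V0_lv": 4.81024258816221,
  "R_ra_rv": 8.12794405811259,
  "R_rv_pa": 5.88906914473953,
  "R_la_lv": 9.61668654625442,
  "R_lv_ao": 12.8656537242605,
  "L_ra_rv": 0.23395445245044,
  "L_rv_pa": 0.104539312049407,
  "L_la_lv": 0.327195463420041,
  "L_lv_ao": 0.174730257893147,
  "C_ao": 0.00106573136829587,
  "C_sys": 0.0252886922409155,
  "R_sys_a": 1200.0251144189,
  "R_sys_v": 197.926934459934,
  "C_pa": 0.00560717413820414,
  "R_pa": 107.022640022883,
  "V_ra_ini": 43.3368262077854,
  "V_rv_ini": 165.885233830473,
  "V_la_ini": 44.3955361880275,
  "V_lv_ini": 192.249118389954,
  "Q_ra_rv_ini": 114.464659543547,
  "Q_rv_pa_ini": 7.85380997513499,
  "Q_la_lv_ini": 27.9595943987953,
  "Q_lv_ao_ini": 7.48412035244632,
  "P_ao_ini": 126477.262927713,
  "P_sys_ini": 18693.9347324626,
  "P_pa_ini": 27547.1077578551
}
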