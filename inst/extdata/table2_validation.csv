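qty,token,units,severe,moderate,healthy,sigma
HR,heart_rate2,bpm,80,80,80,3
RAP,ra_pressure,mmHg,15,9,4,0.5
sPAP,pap_systolic,mmHg,50,35,20,1
dPAP,pap_diastolic,mmHg,25,19,12,1
PCW,wedge_pressure,mmHg,25,17,9,1
SBP,systolic_bp_2,mmHg,120,120,120,1.5
DBP,diastolic_bp_2,mmHg,80,80,80,1.5
SVR,systemic_vascular_resistan,dynes.s.cm-5,1800,1575,1350,50
CO,cardiac_output,L/min,3.5,4.375,5.25,0.2
sRV,right_ventricle_systole,mmHg,50,35,20,1
RVEDP,rvedp,mmHg,15,9,4,1
sLV,lv_systole,mmHg,120,120,120,1.5
LVEDP,lvedp,mmHg,25,16,6,2
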