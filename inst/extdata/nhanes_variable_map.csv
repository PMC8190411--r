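source,target
SEQN,id
RIAGENDR,sex
RIDAGEYR,age
RIDRETH3,race
DMDEDUC2,education
INDFMPIR,pir
RIDEXPRG,pregnant
BMXWT,weight_kg
BMXHT,height_cm
PAQ605,vigorous_work
PAQ650,vigorous_rec
DR1TKCAL,energy_day1_kcal
DR2TKCAL,energy_day2_kcal
DR1TZINC,zn_day1_mg
DR2TZINC,zn_day2_mg
DR1TPFAT,pufa_day1_g
DR2TPFAT,pufa_day2_g
LBXLA,serum_la
LBXDGL,serum_dgla
LBXSZN,serum_zn
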