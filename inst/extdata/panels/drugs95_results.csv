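descriptor,lower,upper,star,note
S_mol,300,1000,TRUE,
S_mol_hfob,0,750,TRUE,
V_mol,500,2000,TRUE,
logS_wat,-6.0,0.5,TRUE,
logK_HSA,-1.5,1.5,TRUE,
logBB,-3.0,1.2,TRUE,
Caco2,25,500,TRUE,recommended band; printed guidance <25 poor / >500 great style
MDCK,25,500,TRUE,printed guidance <25 poor / >500 great
Ind_coh,0.0,0.05,TRUE,
Glob,0.75,0.95,TRUE,
QP_polrz,13.0,70.0,TRUE,
logHERG,-5,Inf,TRUE,concern below -5
logK_p,-8.0,-1.0,TRUE,
n_metab,1,8,TRUE,
MW,130,725,TRUE,standard 95%-of-drugs range; editable
logP,-2.0,6.5,TRUE,standard 95%-of-drugs range; editable
HBA,2,20,TRUE,standard 95%-of-drugs range; editable
HBD,0,6,TRUE,standard 95%-of-drugs range; editable
NRB,0,15,TRUE,standard 95%-of-drugs range; editable
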