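alias,canonical
mol.MW,MW
QPlogPo/w,logP
accptHB,HBA
donorHB,HBD
#rotor,NRB
SASA,S_mol
FOSA,S_mol_hfob
volume,V_mol
QPlogS,logS_wat
CIQPlogS,CIlogS_wat
QPlogKhsa,logK_HSA
QPlogBB,logBB
QPPCaco,Caco2
QPPMDCK,MDCK
QPpolrz,QP_polrz
QPlogHERG,logHERG
QPlogKp,logK_p
#metab,n_metab
#stars,stars
CNS,CNS
PercentHumanOralAbsorption,pct_HOA
HumanOralAbsorption,HOA_class
glob,Glob
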