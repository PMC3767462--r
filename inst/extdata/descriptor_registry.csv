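canonical,units,description,aliases
MW,Da,molecular weight,mol.MW|mol_MW|mw
logP,log10,octanol/water partition coefficient,QPlogPo/w|QPlogPow|log P
HBA,count,hydrogen-bond acceptor count,accptHB|nHBA
HBD,count,hydrogen-bond donor count,donorHB|nHBD
NRB,count,rotatable bond count,#rotor|rotor|n_rot
S_mol,A^2,total solvent-accessible surface area (1.4 A probe),SASA|Smol
S_mol_hfob,A^2,hydrophobic solvent-accessible surface area,FOSA|Smol_hfob
V_mol,A^3,solvent-accessible molecular volume,volume|Vmol
logS_wat,log10 mol/L,aqueous solubility,QPlogS|logS
CIlogS_wat,log10 mol/L,conformation-independent aqueous solubility,CIQPlogS
logK_HSA,log10,human serum albumin binding constant,QPlogKhsa|logKhsa
logBB,log10,blood/brain partition coefficient,QPlogBB|log B/B|logB/B
Caco2,nm/s,apparent Caco-2 cell permeability,QPPCaco|BIP_Caco-2|Caco-2
MDCK,nm/s,apparent MDCK cell permeability,QPPMDCK
Ind_coh,dimensionless,cohesion interaction index HBA*HBD/S_mol,Indcoh|IndCoh
Glob,dimensionless,globularity 4*pi*r^2/S_mol,glob|globularity
QP_polrz,A^3,predicted polarizability,QPpolrz|polrz
logHERG,log10,predicted IC50 for HERG K+ channel blockage,QPlogHERG
logK_p,log10 cm/h,predicted skin permeability,QPlogKp|logKp
n_metab,count,predicted number of metabolic reactions,#metab|metab
stars,count,descriptors outside the 95%-of-drugs ranges,#stars
CNS,score,predicted CNS activity (-2 inactive .. +2 active),CNS_score
pct_HOA,%,predicted percent human oral absorption,PercentHumanOralAbsorption|%HumanOralAbsorption
HOA_class,class,qualitative oral absorption (1 low / 2 medium / 3 high),HumanOralAbsorption
Jm,ug/cm^2/h,maximum transdermal transport rate,
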