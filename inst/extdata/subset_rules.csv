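subset,descriptor,comparator,value,value2
drug_like,MW,lt,500,
drug_like,logP,lt,5,
drug_like,HBD,le,5,
drug_like,HBA,le,10,
lead_like,MW,between,150,350
lead_like,logP,le,4,
lead_like,HBD,le,3,
lead_like,HBA,le,6,
fragment_like,MW,le,250,
fragment_like,logP,between,-2,3
fragment_like,HBD,lt,3,
fragment_like,HBA,lt,6,
fragment_like,NRB,lt,3,
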