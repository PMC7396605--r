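# position-parameter registry for AKIE computation
# n: atoms of the element in the molecule; x: atoms at reactive positions;
# z: indistinguishable reactive sites (intramolecular competition)
# provenance: "literature" = as published for D. mccartyi BTF08 assays;
# "reconstructed" = inferred as the unique small-integer triple consistent
# with the published concerted chlorine AKIE for 1,2-DCA
compound,element,mechanism,n,x,z,provenance
PCE,C,one_step,2,1,4,literature
cDCE,C,one_step,2,1,2,literature
VC,C,one_step,2,1,1,literature
"1,2-DCA",C,concerted,2,2,2,literature
"1,2-DCA",C,stepwise,2,1,2,literature
PCE,Cl,one_step,4,1,4,literature
cDCE,Cl,one_step,2,1,2,literature
VC,Cl,one_step,1,1,1,literature
"1,2-DCA",Cl,concerted,2,2,2,reconstructed
"1,2-DCA",Cl,stepwise,2,1,2,literature
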