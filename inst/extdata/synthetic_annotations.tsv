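symbol	relevance	secreted	tags
AMH	TRUE	TRUE	tgf-beta family; amhr2 ligand
CXCL11	TRUE	TRUE	chemokine; cxcr3 ligand
EPGN	TRUE	TRUE	egfr ligand
FAM3C	TRUE	TRUE	cytokine-like; emt
GDNF	TRUE	TRUE	neurotrophic factor; ret ligand
LIF	TRUE	TRUE	il-6 family; stat3
TGFA	TRUE	TRUE	egfr ligand
TNFAIP2	TRUE	TRUE	tnf-induced; angiogenesis
TNFSF12	TRUE	TRUE	tweak; fn14 ligand
ACTB	FALSE	FALSE	cytoskeleton
GAPDH	FALSE	FALSE	glycolysis
VIM	TRUE	FALSE	intermediate filament; emt
CD68	TRUE	FALSE	macrophage marker; membrane
NOTCH1	TRUE	FALSE	receptor; membrane
CCL2	TRUE	TRUE	monocyte chemoattractant
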