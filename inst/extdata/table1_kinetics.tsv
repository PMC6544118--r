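enzyme_gene	k_cat	k_cat_organism	K_M	K_M_organism	homology_pct
ArgB	4.9	Saccharomyces cerevisiae	1.3	Escherichia coli	56
ArgC	14	Escherichia coli	0.4	Escherichia coli
ArgH	4.9	Anas platyrhynchos	0.4	Anas platyrhynchos	75
BioB	0.0039	Escherichia coli	0.002	Escherichia coli
BioF	0.05825	Escherichia coli	0.025	Escherichia coli
BioC	98.334	Bacillus cereus	0.00108	Bacillus cereus	62
GuaB	13	Escherichia coli	0.061	Escherichia coli
GuaA	23	Escherichia coli	0.053	Escherichia coli
AceB			0.022	Escherichia coli
AceA			0.063	Escherichia coli
BetA			1.5	Escherichia coli
BetB			1.8	Escherichia coli
UxuA			4.79	Escherichia coli
UxuB			1	Escherichia coli
DadA			30	Escherichia coli
DadX			3.03	Escherichia coli
ProB			1.2	Pseudomonas aeruginosa	74
ProA			300	Escherichia coli
OtsA			1	Thermoplasma acidophilum	65
OtsB			0.61	Escherichia coli
CysC			0.0005	Escherichia coli
CysD+CysN			0.0045	Thiobacillus denitrificans	67
PurD			0.03	Escherichia coli
PurH			0.082	Methanocaldococcus jannaschii	50
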