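function_name	cycle	formula
fermentation	carbon	pta AND ackA OR adhE OR ldhA
organic_carbon_oxidation	carbon	gapA OR porA OR korA
ethanol_oxidation	carbon	adhP OR exaA
acetogenesis_wl	carbon	acsB AND fthfs
acetate_oxidation	carbon	acs OR ackA AND pta
methanogenesis	carbon	mcrA OR mtaB AND mtbA
hydrogen_generation	carbon	hycE OR hydA
hydrogen_oxidation	carbon	hyaB OR hybC OR hydB AND hydG
iron_reduction	other	mtrB OR omcB
sulfate_reduction	sulfur	dsrA AND dsrB OR aprA AND sat
sulfur_oxidation	sulfur	soxB OR sqr OR fccB
denitrification	nitrogen	narG OR napA OR nirK OR nirS OR norB OR nosZ
nitrogen_fixation	nitrogen	nifH
nitrification	nitrogen	amoA AND hao
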