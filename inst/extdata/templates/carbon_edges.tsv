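function_name	anchor_id	substrate	product
organic_carbon_oxidation	organic_carbon_oxidation_w	Organic C	CO2
fermentation	fermentation_w	Organic C	Acetate
ethanol_oxidation	ethanol_oxidation_w	Ethanol	Acetate
acetogenesis_wl	acetogenesis_wl_w	CO2	Acetate
acetate_oxidation	acetate_oxidation_w	Acetate	CO2
methanogenesis	methanogenesis_w	CO2	CH4
hydrogen_generation	hydrogen_generation_w	Organic C	H2
hydrogen_oxidation	hydrogen_oxidation_w	H2	H2O
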