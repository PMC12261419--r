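function_name	anchor_id	substrate	product
sulfate_reduction	sulfate_reduction_w	SO4 2-	H2S
sulfur_oxidation	sulfur_oxidation_w	H2S	SO4 2-
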