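function_name	anchor_id	substrate	product
nitrogen_fixation	nitrogen_fixation_w	N2	NH3
nitrification	nitrification_w	NH3	NO3-
denitrification	denitrification_w	NO3-	N2
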