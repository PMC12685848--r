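gene	star	tag_rsids	function_class	activity_value	deletion
CYP2D6	*1		normal	1	FALSE
CYP2D6	*2	rs16947	normal	1	FALSE
CYP2D6	*3	rs35742686	none	0	FALSE
CYP2D6	*4	rs3892097,rs1065852	none	0	FALSE
CYP2D6	*5		none	0	TRUE
CYP2D6	*6	rs5030655	none	0	FALSE
CYP2D6	*10	rs1065852	decreased	0.25	FALSE
CYP2D6	*41	rs28371725,rs16947	decreased	0.5	FALSE
CYP2C19	*1		normal	NA	FALSE
CYP2C19	*2	rs4244285	none	NA	FALSE
CYP2C19	*3	rs4986893	none	NA	FALSE
CYP2C19	*17	rs12248560	increased	NA	FALSE
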