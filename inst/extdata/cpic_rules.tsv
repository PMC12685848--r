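gene	phenotype	drug	action	strength
CYP2D6	IM	paroxetine	lower_start_slower_titration	optional
CYP2D6	IM	amitriptyline	reduce_25	moderate
CYP2D6	IM	nortriptyline	reduce_25	moderate
CYP2D6	PM	paroxetine	reduce_50	moderate
CYP2D6	PM	vortioxetine	reduce_50	moderate
CYP2D6	PM	fluvoxamine	reduce_50	optional
CYP2D6	PM	venlafaxine	alternative_drug	optional
CYP2D6	PM	amitriptyline	alternative_drug	strong
CYP2D6	PM	nortriptyline	alternative_drug	strong
CYP2D6	UM	paroxetine	alternative_drug	moderate
CYP2D6	UM	venlafaxine	alternative_drug	optional
CYP2D6	UM	vortioxetine	alternative_drug	optional
CYP2D6	UM	amitriptyline	alternative_drug	strong
CYP2D6	UM	nortriptyline	alternative_drug	strong
CYP2C19	IM	escitalopram	lower_start_slower_titration	moderate
CYP2C19	IM	sertraline	lower_start_slower_titration	moderate
CYP2C19	PM	escitalopram	reduce_50	strong
CYP2C19	PM	sertraline	reduce_50	moderate
CYP2C19	PM	amitriptyline	reduce_50	moderate
CYP2C19	UM	escitalopram	alternative_drug	strong
CYP2C19	UM	sertraline	alternative_drug	moderate
CYP2C19	UM	amitriptyline	alternative_drug	optional
CYP2C19	RM	escitalopram	consider_higher_or_alternative	optional
CYP2C19	RM	amitriptyline	consider_higher_or_alternative	optional
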