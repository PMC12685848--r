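drug	gene
sertraline	CYP2C19
escitalopram	CYP2C19
citalopram	CYP2C19
paroxetine	CYP2D6
venlafaxine	CYP2D6
fluoxetine	CYP2D6
fluvoxamine	CYP2D6
vortioxetine	CYP2D6
nortriptyline	CYP2D6
amitriptyline	CYP2C19
amitriptyline	CYP2D6
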