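# internal	external
upper outer quadrant	uoq
upper inner quadrant	uiq
lower outer quadrant	loq
lower inner quadrant	liq
left breast	lt breast
right breast	rt breast
left axilla	lt axilla
right axilla	rt axilla
axillary tail	axillary tail
central breast	central
periareolar region	periareolar
retroareolar region	retroareolar
subareolar region	subareolar
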