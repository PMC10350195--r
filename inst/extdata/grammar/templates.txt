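# finding-line templates; signature = slots present
# S = subtype, G = grade, P = position
SGP	- {subtype} , {grade} , involving the {position} .
SGP	- {subtype} , {grade} , located in the {position} .
SGP	{position} : {subtype} , {grade} .
SGP	- {subtype} , {grade} , identified at the {position} .
SG	- {subtype} , {grade} .
SG	- {subtype} , {grade} ( see comment ) .
SG	diagnosis : {subtype} , {grade} .
SP	- {subtype} , involving the {position} .
SP	- {subtype} , located in the {position} .
SP	{position} : {subtype} .
S	- {subtype} .
S	- {subtype} ( see comment ) .
S	diagnosis : {subtype} .
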