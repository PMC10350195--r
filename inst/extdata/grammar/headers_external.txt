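histopathology report :
b - breast core biopsy :
core biopsy , consult material from national reference laboratory :
specimen received : breast tissue .
tru - cut biopsy of breast lump :
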