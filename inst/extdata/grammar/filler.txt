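margins : not involved .
margins are free of atypia .
microcalcifications associated with the lesion .
no microcalcifications are identified .
er : positive , pr : positive .
er : negative , pr : negative .
her2 : equivocal by immunohistochemistry .
size : {num} cm in greatest dimension .
see comment and synoptic report .
the specimen was entirely submitted for microscopic examination .
correlation with imaging findings is recommended .
biopsy site changes are present .
skin and nipple are unremarkable .
lymphovascular invasion is not identified .
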