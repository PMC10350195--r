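# bundled pathology-report synonym groups; words on one line are mutual synonyms
tumor	tumour	neoplasm
lesion	mass	nodule
shows	demonstrates	reveals	exhibits
seen	identified	noted	observed	present
margin	edge
margins	edges
specimen	sample
consistent	compatible
involving	infiltrating
adjacent	nearby
focal	localized
focally	locally
prominent	conspicuous
multiple	several	numerous
small	tiny
large	extensive
findings	features
examined	evaluated	reviewed
submitted	received
performed	done
recommended	advised
unremarkable	uninvolved
benign	innocuous
malignant	cancerous
scattered	dispersed
diffuse	widespread
marked	pronounced
mild	slight
moderate	intermediate
evidence	indication
changes	alterations
associated	accompanying
surrounding	adjoining
positive	reactive
negative	nonreactive
biopsy	bx
excision	resection
report	summary
diagnosis	impression
correlation	comparison
dimension	measurement
greatest	largest
entirely	completely
region	area	zone
guided	directed
criteria	requirements
proliferation	growth
atypia	atypicality
invasion	infiltration
carcinoma	cancer
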