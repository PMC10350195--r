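high nuclear grade
intermediate nuclear grade
low nuclear grade
low to intermediate nuclear grade
intermediate to high nuclear grade
high grade
intermediate grade
low grade
nuclear grade 1
nuclear grade 2
nuclear grade 3
histologic grade 1
histologic grade 2
histologic grade 3
well differentiated
moderately differentiated
poorly differentiated
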