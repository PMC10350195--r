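- showing ductal proliferation , which fall short of the criteria for {subtype} .
- no evidence of {subtype} .
- negative for {subtype} .
- there is no {subtype} identified .
- benign breast tissue , negative for {subtype} .
- {subtype} is not identified in the sampled tissue .
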