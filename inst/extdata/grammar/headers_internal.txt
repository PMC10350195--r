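surgical pathology report . final diagnosis :
breast , needle core biopsy :
breast , segmental excision :
breast , stereotactic core biopsy :
specimen : breast tissue , ultrasound guided core biopsy .
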