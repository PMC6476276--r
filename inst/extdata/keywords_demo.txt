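# demo keyword list: one keyword per line, '#' starts a comment
vaccine
vaccines
vaccination
vaxx
immunization
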