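010001
000001
101010
001111
110000
990101
210110
011099
222211
111001
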