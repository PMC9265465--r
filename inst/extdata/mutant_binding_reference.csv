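compound,energy
MOX,-49.445
Derivative-10,-73.608
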