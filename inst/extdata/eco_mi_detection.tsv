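eco	mi
eco:0005805	mi:0018
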