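filter	completed
cluster	completed
classify	completed
evidence	completed
uarna	completed
orthology	completed
conservation	completed
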