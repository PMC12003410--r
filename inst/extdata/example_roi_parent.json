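{"kind":"parent","polygon":[[10,100],[499,100],[499,365],[10,365]]}
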