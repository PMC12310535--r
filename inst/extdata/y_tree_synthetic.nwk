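(((O2a1,O2a2)O2a,O1b)O2,(C2b,C2c)C2,N1a)ROOT;
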