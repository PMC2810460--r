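mdb001 G CALC B 500 500 10
mdb003 D NORM
mdb005 F CALC M 283 200 15
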