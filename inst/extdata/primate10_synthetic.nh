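(((((((human:0.0067,chimp:0.0068):0.0022,gorilla:0.0088):0.0094,orangutan:0.0183):0.0143,(macaque:0.0074,baboon:0.0074):0.0296):0.0220,marmoset:0.0661):0.0300,tarsier:0.1370):0.0240,(mouse_lemur:0.0920,bushbaby:0.1062):0.0280);
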