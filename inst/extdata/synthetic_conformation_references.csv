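id,state,d,delta
synthetic_closed_1,closed,11.5,32
synthetic_closed_2,closed,12.5,35
synthetic_tight_1,tight,15.5,41
synthetic_tight_2,tight,16.5,44
synthetic_loose_1,loose,21.0,50
synthetic_loose_2,loose,22.5,53
synthetic_open_1,open,29.0,63
synthetic_open_2,open,31.0,67
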