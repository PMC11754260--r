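pattern	ingredient
BREZTRI	BUD/GLY/FOR
BUDESONIDE/GLYCOPYRRONIUM/FORMOTEROL	BUD/GLY/FOR
^BUD/GLY/FOR$	BUD/GLY/FOR
TRELEGY	FF/UMEC/VI
FLUTICASONE FUROATE/UMECLIDINIUM/VILANTEROL	FF/UMEC/VI
^FF/UMEC/VI$	FF/UMEC/VI
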