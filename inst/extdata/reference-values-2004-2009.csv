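icpc,a_ref,b_ref,c_ref,source
H71,,42,,OOH 2004-2009
R75,,23,,OOH 2004-2009
U71,,40,,OOH 2004-2009
R78,,34,,OOH 2004-2009
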