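# {comment}
! PBE0 D3 def2-SV(P) TightSCF Opt
*xyz {charge} {multiplicity}
{coords}
*
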