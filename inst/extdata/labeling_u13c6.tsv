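# Uniform 13C6-glucose growth: every carbon fully labeled.
restype	atom	fraction
*	*	1.0
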