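# Causal/regulatory connective words linking a gene to an event keyword.
induce
induces
induced
inhibit
inhibits
inhibited
suppress
suppresses
suppressed
promote
promotes
promoted
activate
activates
activated
repress
represses
repressed
mediate
mediates
mediated
modulate
modulates
modulated
enhance
enhances
enhanced
stimulate
stimulates
stimulated
attenuate
attenuates
attenuated
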