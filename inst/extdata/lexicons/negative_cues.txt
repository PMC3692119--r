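# Cues marking purpose/method statements or negation rather than results:
# to-infinitive purpose phrases, verbs of studying, and negation words.
to determine
to find
to assess
to investigate
to examine
to evaluate
to elucidate
to explore
to test
to study
not
never
no
cannot
without
study
studied
studies
examine
examined
investigate
investigated
assess
assessed
evaluate
evaluated
analyze
analyzed
analyse
analysed
survey
surveyed
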