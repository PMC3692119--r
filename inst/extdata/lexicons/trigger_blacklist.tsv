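# event_type	word
# Trigger words that almost always signal a false event of the given type.
transcription	described
transcription	derived
transcription	prescribed
transcription	transition
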