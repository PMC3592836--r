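sample	novel_isoforms	known_transcripts
hybrid	8579	38178
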