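sample	reads_generated	reads_mapped	reads_unique
tiger	82479484	41074430	31028999
tawny	70915736	44304273	35089656
hybrid	90401656	51003170	39219548
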