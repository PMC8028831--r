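# ancestral genome: NOT-performing single-h-copy replicator, gestation 471 cycles
wEyopcuyAcccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccccczvfcaxgab
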