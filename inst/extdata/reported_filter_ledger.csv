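step,loci_in,loci_removed,loci_out
clone_dedupe,19666,8079,11587
quality_thresholds,11587,691,10896
hwe,10896,7,10889
monomorphic,10889,99,10790
ld,10790,107,10683
outlier_split,10683,1059,9624
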