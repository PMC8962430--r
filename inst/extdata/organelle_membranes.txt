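# Organelle-membrane keywords that disqualify a protein from
# plasma-membrane candidacy when it lacks an explicit "cell membrane"
# annotation. Lower-case substring match against each membrane keyword.
# Edit freely: this list is configuration, not code.
mitochondrion membrane
mitochondrion inner membrane
mitochondrion outer membrane
mitochondrial membrane
endoplasmic reticulum membrane
endoplasmic reticulum-golgi intermediate compartment membrane
golgi apparatus membrane
golgi membrane
nucleus membrane
nucleus inner membrane
nucleus outer membrane
nuclear membrane
lysosome membrane
endosome membrane
early endosome membrane
late endosome membrane
recycling endosome membrane
peroxisome membrane
melanosome membrane
vacuole membrane
autophagosome membrane
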