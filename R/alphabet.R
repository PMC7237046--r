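# package-level constants (this file must sort first)
BASES <- c("A", "C", "G", "U")
NUC_PAIRS <- t(utils::combn(BASES, 2))  # the 6 unordered base pairs
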