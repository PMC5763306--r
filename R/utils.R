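# locale-independent character sort: iteration orders feed seeded RNG draws
# and tie-breaks, so they must not depend on LC_COLLATE
sort_c <- function(x) sort(x, method = "radix")
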