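# Shared constants; this file must sort first so every module sees them.

# Canonical analyte order: the three tea methylxanthines, then the two
# tobacco markers.
XENO_ANALYTES <- c("theobromine", "caffeine", "theophylline",
                   "nicotine", "cotinine")
XENO_METHYLXANTHINES <- c("theobromine", "caffeine", "theophylline")
XENO_TOBACCO <- c("nicotine", "cotinine")
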