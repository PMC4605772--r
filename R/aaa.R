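# Shared internal constants (sourced first).

# Cell order used throughout: matches the engine's state layout.
.cells <- c("AIYL", "AIYR", "AIZL", "AIZR", "SMBDL", "SMBDR", "SMBVL", "SMBVR")
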