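utils::globalVariables(c("group", "p05", "q25", "median", "q75", "p95",
                         "value"))
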