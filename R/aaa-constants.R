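# Shared constants (file named so it sources before the modules that use
# them at top level).

.DEFAULT_NA_TOKENS <- c("", "NA", "na", "NaN")
.DEFAULT_MAX_LEVELS <- 5L
.TRUE_TOKENS  <- c("TRUE", "True", "true", "T")
.FALSE_TOKENS <- c("FALSE", "False", "false", "F")
.ROLES <- c("numeric", "categorical", "boolean", "identifier", "tooltip")
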