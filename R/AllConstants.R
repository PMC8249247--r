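## Panel-wide constants, defined first in the collation order because class
## prototypes and model defaults reference them at load time.

## The nine-gene panel, in the panel's canonical order.
.PANEL_GENES <- c("TP53", "CTNNB1", "ARMC5", "PRKAR1A", "ZNRF3",
                  "RB1", "APC", "MEN1", "RPL22")

## Closed effect-class taxonomy; UNKNOWN is the sink for unrecognized labels.
.MUTATION_TYPES <- c("NONSYNONYMOUS_SNV", "SYNONYMOUS_SNV", "STOPGAIN",
                     "STOPLOSS", "FRAMESHIFT_DELETION", "FRAMESHIFT_INSERTION",
                     "NONFRAMESHIFT_DELETION", "NONFRAMESHIFT_INSERTION",
                     "SPLICING", "INTRONIC", "UTR5", "UTR3", "UNKNOWN")

## Effect classes treated as biologically significant by default.
## FRAMESHIFT_INSERTION is included for symmetry with deletions even though
## none were observed in the study cohort.
.SIGNIFICANT_TYPES <- c("NONSYNONYMOUS_SNV", "STOPGAIN", "STOPLOSS",
                        "FRAMESHIFT_DELETION", "FRAMESHIFT_INSERTION",
                        "SPLICING")

.GROUP_LEVELS <- c("ACC", "ACA", "NORMAL")
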