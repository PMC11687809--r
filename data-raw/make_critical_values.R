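# Regenerate the packaged asymptotic critical-value table.
# Run from the repository root after installing the package:
#   Rscript data-raw/make_critical_values.R
library(geomgof)
tab <- critical_value_table(c("w2", "a2"), estimated = TRUE, verbose = TRUE)
write_cv_table(tab, file.path("inst", "extdata", "critical_values.csv"))
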