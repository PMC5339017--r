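# Shared fixtures. SYNTHETIC_CTS1 is a synthetic stand-in guide (20 nt, 60%
# GC, typical of fluorescent-reporter assays) used wherever a fixed
# representative spacer is needed; it is not a published sequence.
SYNTHETIC_CTS1 <- "GGUCGACCUCGAGUCAGUCA"

fixture_spacer <- function(name = "cts1_synthetic", seq = SYNTHETIC_CTS1) {
  spacer_record(name, seq)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

csy4_as <- function(mode) {
  u <- cleaving_units()$csy4
  u$graft_mode <- mode
  u
}
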