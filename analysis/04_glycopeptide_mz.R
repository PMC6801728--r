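#!/usr/bin/env Rscript
## Monoisotopic m/z ladder of the TSR2 tryptic peptide of C. elegans UNC-5:
## the [M+3H]3+ ions of the unmodified, mono- and di-C-mannosylated species
## (both cysteines carbamidomethylated).

suppressPackageStartupMessages(library(gtctopo))

dir.create("results", showWarnings = FALSE)
peptide <- "LDGGWSSWSDWSACSSSCHR"

## confirm the peptide is a tryptic product (flanked by cleavage sites)
parent_digest <- tryptic_digest(paste0("AAK", peptide, "AAA"), 0)
stopifnot(peptide %in% parent_digest$peptide)

ladder <- run_mz(peptide, max_hex = 2, charges = 3,
                 out = "results/glycopeptide_ladder.tsv")
print(ladder)
cat(sprintf("di-mannosylated [M+3H]3+ at m/z %.2f; +1 hexose spacing %.4f Th at z = 3\n",
            ladder$mz[ladder$hexoses == 2],
            diff(ladder$mz[order(ladder$hexoses)])[1]))
cat("wrote results/glycopeptide_ladder.tsv\n")
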