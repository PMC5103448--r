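#!/usr/bin/env Rscript
# Run the full mining protocol on the simulated transcriptome from
# analysis/01_simulate.R: six-frame ORF enumeration (>50 aa), evidence
# vote (homeodomain profile + reference k-mer sources), one selected CDS
# per transcript, 100%-identity deduplication, homeodomain localization
# and diagnostic-motif classification. Writes the standard report files
# and scores recovery against the simulation truth table.

suppressMessages(library(hoxminer))

transcripts <- read_fasta("results/transcripts.fna", "nt")
truth <- read_tsv_report("results/truth.tsv")
truth[is.na(truth)] <- ""  # empty strings survive the TSV round-trip as NA

res <- run_pipeline(transcripts, pipeline_config(seed = 20160915L))
write_pipeline_reports(res, "results/pipeline", truth)

cat("stage summary:\n")
print(res$summary, row.names = FALSE)
cat("\nassigned labels:\n")
print(res$label_counts[res$label_counts > 0])

ev <- evaluate_against_truth(res, truth)
by_group <- aggregate(recovered ~ planted_group, ev, mean)
cat("\nper-label recovery (fraction of planted transcripts",
    "classified to their label):\n")
print(by_group, row.names = FALSE)
cat("\nnote: groups whose diagnostic residues are not printed in the",
    "default catalog (placeholder-only slots) are reported AMBIGUOUS or",
    "UNCLASSIFIED by design; see results/pipeline/classified.tsv\n")
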