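#!/usr/bin/env Rscript
# Visit-level quality control: apply the eight FIV/OTV/FRV rules to both
# herds and tabulate per-rule exclusions.

library(pigfcr)
train <- readRDS("scratch/analysis/train_sim.rds")
valid <- readRDS("scratch/analysis/valid_sim.rds")

qc_tr <- apply_qc(train$events)
qc_va <- apply_qc(valid$events)
print(qc_tr$report)
print(qc_va$report)

saveRDS(list(train = qc_tr, valid = qc_va), "scratch/analysis/qc.rds")
write_qc_report(qc_tr$report, "results/02_qc_train.txt")
write_qc_report(qc_va$report, "results/02_qc_valid.txt")

# recall against the generator's injected anomaly labels
key <- function(d) paste(d$pig_id, d$day, d$visit)
removed <- key(train$events[qc_tr$report$removed_index, ])
injected <- key(train$anomalies)
cat(sprintf("\nInjected anomalies removed: %d/%d (%.1f%% recall)\n",
            sum(injected %in% removed), length(injected),
            100 * mean(injected %in% removed)))
cat("All removals match an injected anomaly:",
    all(removed %in% injected), "\n")
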