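#!/usr/bin/env Rscript
# Stage 2 — scarring outcomes.
# Computes day-40 collagen and fibroblast fold changes versus the
# normal-healing reference, assigns the four-way class (normal / mild /
# severe / excluded) and the collagen-only binary label, and reports the
# class mix.
library(scarscreen)

cohort <- readRDS("results/cache/cohort.rds")
labels <- label_cohort(cohort)
write.csv(labels, "results/demo/labels.csv", row.names = FALSE)

counts <- table(labels$class4)
message("class counts: ",
        paste(names(counts), as.integer(counts), sep = "=",
              collapse = ", "))
message("binary: ",
        paste(names(table(labels$binary)),
              as.integer(table(labels$binary)), sep = "=", collapse = ", "))
message("fold-change medians: collagen ",
        signif(median(labels$fc_col), 3), ", fibroblast ",
        signif(median(labels$fc_fib), 3))
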