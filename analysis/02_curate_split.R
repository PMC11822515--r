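#!/usr/bin/env Rscript
# Stage 2: curate NOEC endpoints into binary classes and split the data.
#
# Applies the breakpoint rules (100 mg/kg) to the NOEC text records,
# discards breakpoint-straddling intervals, sets aside an external test
# set of 147 compounds by random sampling, and keeps the remainder as the
# modeling set.

suppressPackageStartupMessages(library(wormtox))

seed <- 1
dm <- read_descriptor_csv("results/data/descriptors.csv")
noec <- utils::read.csv("results/data/noec.csv")
records <- lapply(seq_len(nrow(noec)), function(i)
  parse_noec(noec$noec[i], noec$compound_id[i]))
cls <- assign_classes(records)
cat(sprintf("curation: %d toxic, %d nontoxic, %d discarded\n",
            sum(cls == "toxic"), sum(cls == "nontoxic"),
            sum(cls == "discard")))

keep <- cls != "discard"
curated <- descriptor_matrix(dm$x[keep, , drop = FALSE], labels = cls[keep],
                             compound_id = dm$compound_id[keep])
test_size <- min(147, nrow(curated$x) - 1)
sp <- split_dataset(curated, test_size, seed = derive_seed(seed, "split"))
cat(sprintf("split: %d modeling / %d test compounds\n",
            nrow(sp$modeling$x), nrow(sp$test$x)))
cat(sprintf("modeling pool: %d toxic / %d nontoxic\n",
            class_counts(sp$modeling)[["toxic"]],
            class_counts(sp$modeling)[["nontoxic"]]))

write_descriptor_csv(sp$modeling, "results/modeling_set.csv")
write_descriptor_csv(sp$test, "results/test_set.csv")
cat("wrote results/modeling_set.csv and results/test_set.csv\n")
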