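#!/usr/bin/env Rscript
# Stage 3: score the focal-branch substitution analysis against the truth.
#
# Stage 2 already enumerated replacements between the two reconstructed
# ancestors and applied the descendant-conservation filter; this stage
# compares that event list with the true events (from the recorded
# ancestral sequences) and reports the recovery rate, plus the identity
# report conventions.

library(paleoprot)

fix <- "results/fixtures"
asr <- "results/asr"
stopifnot(file.exists(file.path(asr, "substitution_events.tsv")))

events <- utils::read.delim(file.path(asr, "substitution_events.tsv"))
cat("Inferred replacements on the focal branch:", nrow(events), "\n")
cat("Retained by the all-but-one conservation filter:",
    sum(events$retained), "\n")

tree <- read_tree(file.path(fix, "tree.nwk"))
truth <- read_alignment(file.path(fix, "true_ancestors.fasta"))
manifest <- jsonlite::read_json(file.path(asr, "manifest.json"))
node_a <- clade_node(tree, unlist(manifest$config$ancestor_a$leaves))
node_b <- clade_node(tree, unlist(manifest$config$ancestor_b$leaves))
true_ev <- enumerate_substitutions(
  paste(truth$matrix[as.character(node_a), ], collapse = ""),
  paste(truth$matrix[as.character(node_b), ], collapse = ""))
cat("True replacements on that branch:", true_ev$n_events, "\n")

key_inf <- paste(events$column, events$ancestral_state, events$derived_state)
key_tru <- paste(true_ev$events$column, true_ev$events$ancestral_state,
                 true_ev$events$derived_state)
cat(sprintf("Exact event recovery: %.1f%%; column-level: %.1f%%\n",
            100 * mean(key_tru %in% key_inf),
            100 * mean(true_ev$events$column %in% events$column)))

ident <- jsonlite::read_json(file.path(asr, "identity_report.json"))
for (nm in names(ident))
  cat(sprintf("identity %s: %.1f%% (%d/%d)\n", nm,
              ident[[nm]]$percent, ident[[nm]]$n_matches,
              ident[[nm]]$n_denominator))
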