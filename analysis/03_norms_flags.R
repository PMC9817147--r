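#!/usr/bin/env Rscript
# Step 3 — normative bands, deviation flags, and group divergence.
#
# Builds mirror-augmented control bands (mean +/- 1.5 SD), flags every
# participant's variables as low / high / normal / missing, shades the
# cluster-by-lesion-group divergence matrix, and condenses the flags into
# the two group summary measures (BMLD failures; mean B-G divergence).

library(binlat)

metrics <- read.csv(file.path("results", "metrics.csv"))
sessions <- lapply(list.files(file.path("results", "sessions"),
                              pattern = "\\.json$", full.names = TRUE),
                   read_session)
names(sessions) <- vapply(sessions, `[[`, "", "participant_id")

controls <- metrics[metrics$group == "control", ]
bands <- build_bands(controls, augment_mirror = TRUE)
jsonlite::write_json(bands, file.path("results", "norms.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
cat(sprintf("bands from %d controls (mirror-augmented)\n", nrow(controls)))
bm <- bands[bands$variable == "bmld", ]
cat(sprintf("BMLD normal range: %.1f to %.1f dB\n", bm$lo, bm$hi))

clusters <- default_clusters()
flags <- list()
nonconv <- logical(0)
for (i in seq_len(nrow(metrics))) {
  id <- metrics$participant_id[i]
  tin <- sessions[[id]]$tin
  flags[[id]] <- flag_participant(metrics[i, ], bands,
                                  tin_valid = is.na(tin$reason),
                                  clusters = clusters)
  nonconv[id] <- !is.na(tin$reason)
}
flags_long <- do.call(rbind, lapply(names(flags), function(id)
  cbind(participant_id = id, flags[[id]])))
write.csv(flags_long, file.path("results", "flags.csv"), row.names = FALSE)

groups <- setNames(metrics$group, metrics$participant_id)
patients <- metrics$participant_id[metrics$group != "control"]
cm <- cluster_matrix(flags[patients], groups, clusters)
write.csv(cm$counts, file.path("results", "cluster_matrix.csv"),
          row.names = FALSE)
cat("divergence matrix (% deviant cells per lesion group x cluster):\n")
print(round(cm$percent, 1))

summ <- summary_measures(flags, groups, nonconvergent = nonconv,
                         clusters = clusters)
write.csv(summ, file.path("results", "summary.csv"), row.names = FALSE)
cat("group summaries (pooled left/right):\n")
print(summ, digits = 3)
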