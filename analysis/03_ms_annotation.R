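#!/usr/bin/env Rscript
# Flavonol glycoside MS annotation: theoretical ion series vs observed ions.
#
# Predicts the ESI+/ESI- ion series for the six leaf flavonol glycoside
# candidates, compares them with the packaged observed ion catalogue, and
# annotates each compound's observed ion list. Writes results/annotation/.

suppressMessages(library(hopchem))

outdir <- file.path("results", "annotation")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cands <- flavonol_candidates()
pred <- do.call(rbind, lapply(names(cands), function(id) {
  cbind(candidate_id = id,
        rbind(predict_ions(cands[[id]], "positive"),
              predict_ions(cands[[id]], "negative")),
        mass_da = theoretical_mass(cands[[id]]))
}))
write.csv(pred, file.path(outdir, "predicted_ions.csv"), row.names = FALSE)

ions <- load_table3_fixture()
rows <- lapply(split(ions, ions$compound_id), function(g) {
  ranked <- annotate_spectrum(data.frame(mz = g$mz, mode = g$mode),
                              lambda_max_nm = g$lambda_max_nm[1],
                              rt_min = g$rt_min[1])
  data.frame(observed_compound = g$compound_id[1], n_ions = nrow(g),
             top_candidate = ranked$candidate_id[1],
             score = ranked$score[1],
             correct = ranked$candidate_id[1] == g$compound_id[1])
})
ann <- do.call(rbind, rows)
rownames(ann) <- NULL
write.csv(ann, file.path(outdir, "annotation.csv"), row.names = FALSE)

cat("Predicted ion series for", length(cands), "candidates ->",
    file.path(outdir, "predicted_ions.csv"), "\n")
cat(sprintf("Observed ion lists annotated: %d/%d ranked correctly\n",
            sum(ann$correct), nrow(ann)))
mal <- pred[pred$species == "M-CO2-H", ]
cat(sprintf("Diagnostic malonyl CO2 loss at m/z %s (neutral loss 43.99 Da)\n",
            paste(sprintf("%.1f", mal$mz), collapse = ", ")))
print(ann, row.names = FALSE)
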