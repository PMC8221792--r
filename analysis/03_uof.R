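#!/usr/bin/env Rscript
# Stage 3: uptake-objective simulations. For each synthetic dataset the
# uptake of a nonessential metabolite (glucose, glutamine, serine) is
# minimized instead of maximizing growth, with growth and the remaining
# exchange rates fixed to the measured values, and the resulting
# intracellular fluxes are compared with the biomass-objective
# predictions.
#
# Writes to results/: uof_uptakes.tsv (minimal vs measured uptake per
# objective) and uof_agreement.tsv (median relative deviation of the
# mapped intracellular fluxes from the biomass-objective solution).
#
# Usage: Rscript analysis/03_uof.R

suppressMessages(library(maintflux))
stopifnot(file.exists("results/manifest.json"))
manifest <- jsonlite::fromJSON("results/manifest.json")

model <- read_model("results/toy_model.json")
mapping <- read_mapping_table("results/datasets/mapping.tsv")
est <- read.delim("results/matp_estimates.tsv")

objectives <- c("glc__D", "gln__L", "ser__L")
ids <- est$dataset[est$dataset != "noiseless"]

uptakes <- list(); agreement <- list()
for (id in ids) {
  ex <- read_exchange_dataset(sprintf("results/datasets/%s_exchange.tsv", id))
  matp <- est$estimated_matp[est$dataset == id]
  bof <- predict_with_matp(model, ex, matp)
  mb <- map_fluxes(bof, mapping)
  for (obj in objectives) {
    res <- tryCatch(uof_pfba(model, ex, obj, matp = matp),
                    error = function(e) NULL)
    if (is.null(res)) {
      message(id, " / ", obj, ": infeasible, skipped")
      next
    }
    uptakes[[paste(id, obj)]] <- data.frame(
      dataset = id, objective = obj,
      minimal_uptake = res$minimal_uptake,
      measured_uptake = res$measured_uptake,
      n_adjusted = nrow(res$adjusted_constraints))
    mu_ <- map_fluxes(res$fluxes, mapping)
    keep <- abs(mb) > 1e-4
    agreement[[paste(id, obj)]] <- data.frame(
      dataset = id, objective = obj,
      median_re_vs_bof = stats::median(
        abs(mu_[keep] - mb[keep]) / abs(mb[keep])))
  }
}
up <- do.call(rbind, uptakes)
ag <- do.call(rbind, agreement)
write.table(up, "results/uof_uptakes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ag, "results/uof_agreement.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (obj in objectives) {
  sel <- if (is.null(up)) logical(0) else
    up$objective == obj & !is.na(up$measured_uptake) &
    up$measured_uptake != 0
  if (!any(sel)) { message(obj, ": no feasible datasets"); next }
  e <- abs(up$minimal_uptake[sel] - up$measured_uptake[sel]) /
    abs(up$measured_uptake[sel])
  message(obj, ": median |minimal - measured|/|measured| = ",
          signif(stats::median(e), 3),
          " over ", sum(sel), " datasets",
          "; intracellular deviation from biomass objective = ",
          signif(stats::median(ag$median_re_vs_bof[ag$objective == obj]), 3))
}
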