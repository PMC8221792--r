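#!/usr/bin/env Rscript
# Stage 2: grid-search estimation of the maintenance energy from the
# synthetic 13C datasets generated by 01_simulate.R, per dataset and
# jointly, plus the before/after comparison of flux-prediction accuracy.
#
# Writes to results/: matp_estimates.tsv (per-dataset optima),
# matp_profiles.tsv (median relative error vs mATP, the error-profile
# curves), subsystem_accuracy.tsv (R^2 and median RE per central-carbon
# subsystem, without vs with the estimated mATP) and matp_effect.json
# (interaction and likelihood-ratio tests of the constraint's effect).
#
# Usage: Rscript analysis/02_estimate_matp.R

suppressMessages(library(maintflux))
stopifnot(file.exists("results/manifest.json"))
manifest <- jsonlite::fromJSON("results/manifest.json")

model <- read_model("results/toy_model.json")
mapping <- read_mapping_table("results/datasets/mapping.tsv")
ids <- names(manifest$datasets)

datasets <- lapply(ids, function(id) {
  ex <- read_exchange_dataset(sprintf("results/datasets/%s_exchange.tsv", id))
  read_c13_dataset(sprintf("results/datasets/%s_c13.tsv", id), ex)
})
names(datasets) <- ids

grid <- seq(0, 40, 0.25)
estimates <- lapply(datasets, function(d)
  estimate_matp(model, d, mapping, grid = grid))

est_tab <- data.frame(
  dataset = ids,
  true_matp = vapply(ids, function(i) manifest$datasets[[i]]$true_matp, 0),
  estimated_matp = vapply(estimates, `[[`, 0, "optimum"),
  median_re_at_optimum = vapply(estimates, `[[`, 0, "optimum_re"),
  median_re_at_zero = vapply(estimates, function(e)
    e$profile$median_re[e$profile$matp == 0], 0))
write.table(est_tab, "results/matp_estimates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("per-dataset mATP: ",
        paste(signif(est_tab$estimated_matp, 3), collapse = " "),
        " (truth ", manifest$true_matp, ")")

profiles <- do.call(rbind, lapply(ids, function(id) {
  p <- estimates[[id]]$profile
  cbind(dataset = id, p[p$feasible, c("matp", "median_re", "growth")])
}))
write.table(profiles, "results/matp_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

noisy <- ids[ids != "noiseless"]
joint <- estimate_matp_joint(model, datasets[noisy], mapping, grid = grid)
message("joint estimate across ", length(noisy), " datasets: ",
        joint$optimum, " mmol/gDW/h")

## before/after accuracy, pooled over the noisy datasets
pool <- function(matp_by_id) {
  do.call(rbind, lapply(noisy, function(id) {
    d <- filter_small_fluxes(datasets[[id]])
    sol <- predict_with_matp(model, datasets[[id]]$exchange,
                             matp_by_id[[id]])
    mapped <- map_fluxes(sol, mapping)
    data.frame(dataset = id, c13_id = d$fluxes$c13_id,
               subsystem = d$fluxes$subsystem,
               ve = d$fluxes$value, vp = unname(mapped[d$fluxes$c13_id]),
               ci_width = d$fluxes$ci_high - d$fluxes$ci_low)
  }))
}
without <- pool(stats::setNames(rep(0, length(noisy)), noisy))
with_m <- pool(stats::setNames(
  lapply(noisy, function(id) estimates[[id]]$optimum), noisy))

report <- function(tab) {
  key <- paste(tab$dataset, tab$c13_id, sep = ":")
  subsystem_report(stats::setNames(tab$vp, key),
                   stats::setNames(tab$ve, key),
                   stats::setNames(tab$subsystem, key),
                   stats::setNames(tab$ci_width, key))
}
acc <- merge(report(without), report(with_m), by = c("subsystem"),
             suffixes = c("_without_matp", "_with_matp"))
write.table(acc[order(acc$subsystem != "All", acc$subsystem), ],
            "results/subsystem_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("overall median RE: ",
        signif(acc$median_re_without_matp[acc$subsystem == "All"], 3),
        " without mATP -> ",
        signif(acc$median_re_with_matp[acc$subsystem == "All"], 3),
        " with mATP")

eff <- matp_effect_test(without$ve, without$vp, with_m$vp,
                        weights = 1 / pmax(without$ci_width, 1e-6))
jsonlite::write_json(
  list(joint_matp = joint$optimum,
       p_interaction = eff$p_interaction,
       slope_without = eff$slope_without, slope_with = eff$slope_with,
       lr_chi2 = eff$lr_chi2, lr_df = eff$lr_df, lr_p = eff$lr_p),
  "results/matp_effect.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("slope ", signif(eff$slope_without, 3), " -> ",
        signif(eff$slope_with, 3), ", interaction p = ",
        format(eff$p_interaction, digits = 3))
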