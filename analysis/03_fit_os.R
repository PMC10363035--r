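#!/usr/bin/env Rscript
# Step 3: TGI-OS link. Joins the empirical Bayes log(KG) estimates with the
# baseline covariates and OS outcomes, fits the log-normal AFT model by
# censored maximum likelihood, and writes a coefficient table
# (estimate, SE, Wald z, p). Covariates without variation in this trial
# (line of therapy in a first-line study) are dropped from the candidate
# set, and a backward-elimination pass at alpha = 0.01 is reported.

suppressPackageStartupMessages(library(tgios))

ds <- read_trial(file.path("results", "trial"))
fe <- filter_evaluable(ds)
ebes <- read.csv(file.path("results", "tgi", "ebes.csv"),
                 colClasses = c(subject_id = "character"))

design <- os_design(fe$data$covariates, setNames(ebes$log_kg, ebes$subject_id))
os <- fe$data$os[match(design$subject_id, fe$data$os$subject_id), ]

candidates <- c("log_kg", "albumin", "ecog_ge1", "race_asian", "n_met_sites",
                "nlr", "liver_met", "baseline_sld", "line_2plus", "sex_female")
terms <- candidates[vapply(design[candidates],
                           function(x) length(unique(x)) > 1, logical(1))]
if (length(setdiff(candidates, terms))) {
  cat("Dropped constant covariate(s):",
      paste(setdiff(candidates, terms), collapse = ", "), "\n")
}

m <- fit_os(os$os_days, os$event, design, terms)
print(m)

out_dir <- file.path("results", "os")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write.csv(m$coefficients, file.path(out_dir, "os_coefficients.csv"),
          row.names = FALSE)
write_os_model(m, file.path(out_dir, "os_model.json"))

sel <- select_covariates(os$os_days, os$event, design, terms, alpha = 0.01)
el <- attr(sel, "elimination")
if (nrow(el)) {
  cat("Backward elimination at alpha = 0.01 dropped:",
      paste(sprintf("%s (p=%.3f)", el$term, el$p), collapse = ", "), "\n")
} else {
  cat("Backward elimination at alpha = 0.01 kept every candidate\n")
}
cat("Wrote", out_dir, "(os_coefficients.csv, os_model.json)\n")
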