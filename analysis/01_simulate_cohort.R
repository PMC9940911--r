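#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Builds the reversal-learning schedule (three 40-trial sessions, 80%:20%
# contingencies reversing after trial 60), samples a patient cohort tested
# ON and OFF stimulation plus a healthy-control (HC) cohort, and simulates
# choices/decision times from the RLDDM generative loop. All downstream
# stages read the files written here.

suppressPackageStartupMessages(library(rlddm))

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

config <- list(seed = seed, chains = 2L, burn = 1500L, draws = 1500L,
               n_subjects = 18L,
               task = list(p_high = 0.8, trials_per_session = 40L,
                           n_sessions = 3L, reversal_trial = 60L),
               omission_rate = 0.015,
               files = list(trials_patients = "results/trials_patients.tsv",
                            trials_hc = "results/trials_hc.tsv",
                            cohort_params = "results/cohort_params.tsv"))
write_run_config(config, "results/run_config.json")

schedule <- with(config$task, make_schedule(p_high, trials_per_session,
                                            n_sessions, reversal_trial))
print(schedule)

patients <- sample_cohort(cohort_spec(n_subjects = config$n_subjects,
                                      conditions = c("ON", "OFF")),
                          seed = seed)
hc <- sample_cohort(cohort_spec(n_subjects = config$n_subjects,
                                conditions = "HC",
                                group_means = default_group_means()["HC"]),
                    seed = seed + 1L)
hc$subject <- hc$subject + 100L  # keep subject ids disjoint from patients

trials_p <- generate_cohort_data(patients, schedule,
                                 omission_rate = config$omission_rate,
                                 seed = seed + 2L)
trials_h <- generate_cohort_data(hc, schedule,
                                 omission_rate = config$omission_rate,
                                 seed = seed + 3L)

write_trials(trials_p, config$files$trials_patients)
write_trials(trials_h, config$files$trials_hc)
write.table(rbind(patients, hc), config$files$cohort_params,
            sep = "\t", quote = FALSE, row.names = FALSE)

for (d in list(trials_p, trials_h)) {
  om <- tapply(d$omitted, paste(d$subject, d$condition), sum)
  cat(sprintf("%s: %d trials, omissions per dataset %d-%d (mean %.1f)\n",
              paste(unique(d$condition), collapse = "/"), nrow(d),
              min(om), max(om), mean(om)))
}

pe <- cohort_pexplore(trials_p, patients)
cat(sprintf("Generative P(Explore): ON %.3f, OFF %.3f\n",
            mean(pe$p_explore[pe$condition == "ON"]),
            mean(pe$p_explore[pe$condition == "OFF"])))
cat("Stage 1 outputs written under results/\n")
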