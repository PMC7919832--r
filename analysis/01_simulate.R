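#!/usr/bin/env Rscript
# Stage 1: synthesize the study data.
#
# Writes (a) a 30-s ground-truthed recording -- NBHF click trains over
# broadband noise at 576 kHz -- and (b) the study-mimic minute-level count
# and context-annotation tables (~6000 minutes over 50 days). Everything
# downstream (detector training, detection, the context GLMM) runs off
# these files, so the whole analysis is reproducible from one seed.

library(finclick)

out <- "results/simulate"
scenario <- scenario_config(seed = 1L)
paths <- run_simulate(out, scenario,
                      audio = list(duration = 30, sample_rate = 576000,
                                   train_rate_per_min = 12,
                                   snr_db = c(15, 25), noise_level_db = -40,
                                   echo_model = FALSE))

truth <- read.csv(paths$truth)
counts <- read.csv(paths$counts)
cat(sprintf("wrote %s: %d ground-truth clicks in 30 s of audio\n",
            paths$wav, nrow(truth)))
cat(sprintf("wrote %s: %d observation minutes, mean density %.0f clicks/min\n",
            paths$counts, nrow(counts), mean(counts$click_count)))
cat(sprintf("click density range: %d-%d clicks/min\n",
            min(counts$click_count), max(counts$click_count)))
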