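#!/usr/bin/env Rscript
# Growth modelling: per-animal robust regression of BW on day (slope =
# ADG; animals with pseudo-R2 < 0.8 are excluded) and a population
# three-parameter logistic growth curve on the retained animals.

library(pigfcr)
intake <- readRDS("scratch/analysis/intake.rds")
train <- readRDS("scratch/analysis/train_sim.rds")

daily_tr <- daily_records(intake$train$events)
daily_va <- daily_records(intake$valid$events)
gfits_tr <- fit_growth_all(daily_tr)
gfits_va <- fit_growth_all(daily_va)
kept <- gate_animals(gfits_tr)
cat(sprintf("train: %d/%d animals pass the pseudo-R2 >= 0.8 gate\n",
            length(kept), nrow(gfits_tr)))

# ADG recovery against generator truth
truth <- train$truth[match(gfits_tr$pig_id, train$truth$pig_id), ]
cat(sprintf("median |ADG_hat - true slope|: %.4f kg/d\n",
            median(abs(gfits_tr$slope - truth$true_slope), na.rm = TRUE)))

# population growth curve on the age axis
age_df <- data.frame(day = daily_tr$day + train$truth$age_offset[1],
                     bw_kg = daily_tr$bw_kg)
logi <- fit_logistic(age_df)
print(logi)
cat(sprintf("age at half BW_max: %.1f d (BW %.1f kg)\n",
            logi$xmid, logi$bw_max / 2))

saveRDS(list(daily_train = daily_tr, daily_valid = daily_va,
             gfits_train = gfits_tr, gfits_valid = gfits_va,
             retained = kept, logistic = logi),
        "scratch/analysis/growth.rds")
write.csv(data.frame(gfits_tr[, c("pig_id", "slope", "intercept",
                                  "pseudo_r2", "retained")]),
          "scratch/analysis/growth_fits.csv", row.names = FALSE)
write.csv(data.frame(param = c("bw_max", "xmid", "scal", "rss"),
                     value = c(logi$bw_max, logi$xmid, logi$scal, logi$rss)),
          "results/04_logistic.csv", row.names = FALSE)
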