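#!/usr/bin/env Rscript
# How cheap must AB-MRI be? Solves the examination price at which AB-MRI
# (a) becomes outright cost-saving versus DBT and (b) still meets the
# $100,000/QALY willingness-to-pay threshold.

library(screenCEA)
dir.create("results", showWarnings = FALSE)

params <- default_parameters()
lt <- default_life_table()

p_cs <- solve_price_threshold(params, lt, mode = "cost_saving")
p_wtp <- solve_price_threshold(params, lt, mode = "wtp", wtp = params$wtp)
slope <- exam_cost_slope("AB_MRI", params, lt)

cat(sprintf("Discounted attended screening rounds (cost slope): %.4f per $ of exam price\n", slope))
cat(sprintf("AB-MRI is cost-saving below an exam price of        $%.2f\n", p_cs))
cat(sprintf("AB-MRI stays under $100k/QALY up to an exam price of $%.2f\n", p_wtp))
cat(sprintf("(base-case prices: DBT $%.2f, AB-MRI $%.2f)\n",
            params$cost_exam[["DBT"]], params$cost_exam[["AB_MRI"]]))

write.csv(data.frame(mode = c("cost_saving", "wtp_100k"),
                     threshold_price = c(p_cs, p_wtp)),
          "results/price_thresholds.csv", row.names = FALSE)
cat("Wrote results/price_thresholds.csv\n")
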