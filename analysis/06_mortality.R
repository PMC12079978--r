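#!/usr/bin/env Rscript
# Stage 6: Fisher's exact comparison of mortality between the treatment and
# control sites, overall and within sexes, by hypergeometric enumeration
# with conditional-MLE odds ratios.

library(rutmove)

meta <- read_meta("results/data/animals.csv")
meta$died <- meta$fate %in% c("DVC", "unknown", "poached", "other")

tab_of <- function(m) t(vapply(c("treatment", "control"), function(s)
  c(died = sum(m$died[m$site == s]), survived = sum(!m$died[m$site == s])),
  numeric(2)))

rows <- lapply(list(overall = meta, M = meta[meta$sex == "M", ],
                    F = meta[meta$sex == "F", ]), function(m) {
  tab <- tab_of(m)
  ft <- fisher_exact_2x2(tab)
  data.frame(died_treatment = tab[1, 1], died_control = tab[2, 1],
             n_treatment = sum(tab[1, ]), n_control = sum(tab[2, ]),
             odds_ratio = ft$odds_ratio, p_value = ft$p_value)
})
out <- do.call(rbind, rows)
out <- cbind(stratum = rownames(out), out)
write.csv(out, "results/mortality.csv", row.names = FALSE)
print(out, row.names = FALSE)
cat("wrote results/mortality.csv\n")
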