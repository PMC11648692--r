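#!/usr/bin/env Rscript
# Step 5 -- statistical comparison of pipeline options.
#
# N-way ANOVA of the replication metrics over classifier, harmonization and
# feature-subset factors, and a ranked report with Tukey HSD pairwise
# comparisons under Benjamini-Hochberg FDR control (subsets pooled, as the
# headline comparisons do). Replications share data, so p-values are
# approximate.

library(mciharmonix)

res <- read_results("results/evaluation_results.csv")

for (metric in c("f1", "mcc_prime")) {
  for (mode in unique(res$mode)) {
    sub <- res[res$metric == metric & res$mode == mode &
                 res$estimate_type == "nested", ]
    design <- data.frame(response = sub$value,
                         classifier = sub$classifier,
                         harmonization = sub$harmonization,
                         subset = sub$subset)
    an <- nway_anova(design, c("classifier", "harmonization", "subset"))
    cat(sprintf("\n%s / %s mode -- N-way ANOVA:\n", metric, mode))
    print(an, row.names = FALSE)
    rep_out <- compare_report(sub, metric)
    cat("top combinations:\n")
    print(head(rep_out$ranking, 4), row.names = FALSE)
    write.csv(rep_out$ranking,
              sprintf("results/ranking_%s_%s.csv", metric, mode),
              row.names = FALSE)
    if (!is.null(rep_out$pairwise)) {
      write.csv(rep_out$pairwise,
                sprintf("results/pairwise_%s_%s.csv", metric, mode),
                row.names = FALSE)
    }
  }
}

# the optimism diagnostic: direct (tuning) estimates vs nested holdout
f1 <- res[res$metric == "f1", ]
gap <- aggregate(value ~ mode + classifier, f1[f1$estimate_type == "direct", ],
                 mean)$value -
  aggregate(value ~ mode + classifier, f1[f1$estimate_type == "nested", ],
            mean)$value
cat("\nmean direct-minus-nested F1 gap per (mode, classifier):",
    round(gap, 3), "\n")
cat("wrote results/ranking_*.csv and results/pairwise_*.csv\n")
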