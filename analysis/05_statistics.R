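#!/usr/bin/env Rscript
# The statistical comparisons: ipsilateral vs contralateral counts and
# afferent vs efferent strengths by unpaired t-test, and an across-region
# one-way ANOVA with Bonferroni post-hoc on per-"brain" replicate
# strengths (three seeded replicate simulations stand in for the three
# randomly selected brains per injected region).

library(voleconnectome)

counts <- read_counts("results/synthetic/counts.csv")
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

t_ic <- ipsi_contra_test(counts)
cat(sprintf("ipsi vs contra: t(%d) = %.2f, p = %.3g%s\n",
            t_ic$df, t_ic$statistic, t_ic$p_value,
            if (t_ic$significant) " *" else ""))

st <- node_strength(build_connectome(counts))
t_ae <- unpaired_t(st$afferent, st$efferent)
cat(sprintf("afferent vs efferent strength: t(%d) = %.2f, p = %.3g\n",
            t_ae$df, t_ae$statistic, t_ae$p_value))
cat("  (network-wide afferent and efferent totals are equal by construction:\n",
    "  each projection is one region's afferent and another's efferent)\n")
write.csv(rbind(cbind(comparison = "ipsi_vs_contra", t_ic),
                cbind(comparison = "afferent_vs_efferent", t_ae)),
          file.path(out_dir, "t_tests.csv"), row.names = FALSE)

# replicate strengths: 3 seeded simulations = 3 "brains" per region
brains <- lapply(1:3, function(b) {
  sim <- generate_count_matrix(synthetic_spec(hub_index = 2,
                                              seed = 20260920 + b))
  node_strength(build_connectome(sim$counts))$total
})
groups <- setNames(
  lapply(seq_along(vsb_regions()), function(i) sapply(brains, `[`, i)),
  vsb_regions())

fit <- oneway_anova_bonferroni(groups, alpha = 0.05)
cat(sprintf("across-region ANOVA on total strength: F(%d,%d) = %.3f, p = %.3g\n",
            fit$anova$df1, fit$anova$df2, fit$anova$statistic,
            fit$anova$p_value))
write.csv(fit$anova, file.path(out_dir, "anova.csv"), row.names = FALSE)
if (!is.null(fit$pairwise)) {
  sig <- fit$pairwise[fit$pairwise$significant, ]
  cat(sprintf("Bonferroni post-hoc (%d pairs): %d significant at 0.05\n",
              fit$n_pairs, nrow(sig)))
  write.csv(fit$pairwise, file.path(out_dir, "posthoc_bonferroni.csv"),
            row.names = FALSE)
}
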