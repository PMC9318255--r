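#!/usr/bin/env Rscript
# Tetrad stage: Thurstonian analysis of the day-1 discrimination test.
# The study design parameters (similarity margin d' = 1.2, alpha = 0.1,
# target power 0.9) and the simulated panel responses drive an exact-binomial
# difference test, similarity test, d' estimate and panel-size plan.

library(shelfsense)

resp <- utils::read.csv("results/data/tetrad_responses.csv")
n <- nrow(resp); x <- sum(resp$correct)
cat(sprintf("panel: %d assessors, %d correct groupings (Pc = %.3f, chance 1/3)\n",
            n, x, x / n))

diff <- tetrad_difference_test(n, x)
sim <- tetrad_similarity_test(n, x, dprime0 = 1.2)
dhat <- estimate_dprime(n, x)
plan <- tetrad_sample_size(1.2, alpha = 0.1, target_power = 0.9)

cat(sprintf("difference test: exact upper-tail p = %.3f\n", diff$p_value))
cat(sprintf("similarity test vs d'0 = 1.2: p = %.4f, confidence = %.1f%%\n",
            sim$p_value, 100 * sim$confidence))
cat(sprintf("estimated d' = %.3f (se %.3f)\n", dhat$dprime, dhat$se))
cat(sprintf(
  "planning at (d'0 = 1.2, alpha = 0.1, power = 0.9): minimum n = %d (critical value %d, power %.3f)\n",
  plan$n, plan$critical_value, plan$power))

dir.create("results", showWarnings = FALSE)
write_report(list(
  n_assessors = n, n_correct = x,
  difference_p = diff$p_value,
  similarity_p = sim$p_value, similarity_confidence = sim$confidence,
  dprime = dhat$dprime, dprime_se = dhat$se,
  plan = plan[c("n", "critical_value", "power", "pc0")]),
  "results/tetrad.json")
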