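#!/usr/bin/env Rscript
# Directionality: does accumulated adaptive change (path-wise rate) predict
# relative testes mass, and does the effect depend on social mating system?
# Trends models per class on the median rate-scaled tree, with the
# intercept-difference fallback where no slope is significant.

library(ratescape)

tree <- read_newick("results/data/tree.nwk")
traits <- read_trait_table("results/data/traits.csv")
mp <- match_and_prune(tree, traits)
trace <- readRDS("results/cache/vr_trace.rds")

med_tree <- median_scaled_tree(trace)
pw <- pathwise_rates(trace)

rows <- list()
for (grp in levels(droplevels(mp$table$class))) {
  tab <- mp$table[mp$table$class == grp, ]
  # the GLS subsets the scaled tree's covariance by the group's species
  res <- tryCatch(run_trends(tab, med_tree, pw, group = grp),
                  error = function(e) e)
  if (inherits(res, "error")) {
    cat(grp, ": not analysable (", conditionMessage(res), ")\n")
    next
  }
  cat("\n==", grp, "==\n")
  print(res$slope_model)
  if (!is.null(res$intercept_model)) print(res$intercept_model)
  sl <- res$slope_model$slopes
  sl$group <- grp
  sl$model_branch <- res$model_branch
  rows[[grp]] <- sl
  # predicted testes mass at the group's average body mass, per category
  body_bar <- mean(tab$body)
  for (cat_i in sl$category) {
    pr <- predict_trait(res$slope_model, body = body_bar, category = cat_i,
                        pathrate = median(pw$summary$median))
    cat(sprintf("  predicted testes mass (%s, avg body %.0f g): %.2f g\n",
                cat_i, 10^body_bar, pr$grams))
  }
}

dir.create("results", showWarnings = FALSE)
if (length(rows)) {
  utils::write.csv(do.call(rbind, rows), "results/trends_slopes.csv",
                   row.names = FALSE)
  cat("\nWrote results/trends_slopes.csv\n")
}
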