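# Brute-force oracle: evaluate ALL (district, feasible subset) options with
# portfolio_value/option_cost directly, apply the affordability filter, and
# reproduce reconsider()'s rule. Kept deliberately naive (nested loops).
brute_force_choice <- function(pop, ln, i, w, dp, nw, t) {
  cm <- w$params$credit_multiplier
  budget <- pop$wealth[i] + cm * pop$capital[i]
  cands <- rank_candidate_districts(pop, ln, i, w, dp$k_locations)
  best <- NULL
  best_val <- 0
  any_better <- FALSE
  for (d in cands) {
    sub <- district_subsets(w, d, dp$max_layers)
    for (r in seq_len(nrow(sub$S))) {
      layers <- sub$lay[sub$S[r, ] > 0]
      open <- pop$holders[layers] < w$layers$capacity[layers] |
        layers %in% pop$port[[i]]
      if (!all(open)) next
      val <- portfolio_value(pop, ln, i, d, layers, w, dp, nw, t)
      if (val <= 0) next
      any_better <- TRUE
      cost <- as.numeric(option_cost(pop, i, d, layers, w))
      if (cost > budget) next
      if (val > best_val) {
        best_val <- val
        best <- list(district = d, layers = layers, value = val)
      }
    }
  }
  if (!any_better) {
    list(action = "stay", moored = FALSE)
  } else if (is.null(best)) {
    list(action = "stay-moored", moored = TRUE)
  } else {
    list(
      action = if (best$district != pop$district[i]) "move" else "stay",
      moored = FALSE, district = best$district, layers = best$layers,
      value = best$value
    )
  }
}
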