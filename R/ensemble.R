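#' Design of a Monte Carlo simulation experiment
#'
#' Each run draws an emissions scenario uniformly from `scenarios`, a
#' perceived-normal multiplier `m ~ Uniform(0.5, 1.5)`, a credit multiplier
#' `~ Uniform(0, 2)`, and the remaining decision-sensitive parameters from
#' their ranges, then executes a full simulation with seed
#' `seed_base + run index`.
#'
#' @param n_runs number of runs.
#' @param scenarios subset of `c("rcp26", "rcp45", "rcp85")`.
#' @param m_range perceived-normal multiplier range, within `[0.5, 1.5]`.
#' @param credit_range credit multiplier range, within `[0, 2]`.
#' @param other_ranges named list of ranges for `k_locations`, `rho_scale`,
#'   `info_share_prob`, `p_reconsider_mean`.
#' @param seed_base integer; run `r` uses seed `seed_base + r`.
#' @param n_agents,start_year,end_year per-run simulation size and window.
#' @export
experiment_design <- function(n_runs = 40L,
                              scenarios = c("rcp26", "rcp45", "rcp85"),
                              m_range = c(0.5, 1.5),
                              credit_range = c(0, 2),
                              other_ranges = list(
                                k_locations = c(2, 6),
                                rho_scale = c(0.75, 1.25),
                                info_share_prob = c(0.2, 0.8),
                                p_reconsider_mean = c(0.05, 0.15)
                              ),
                              seed_base = 0L,
                              n_agents = 200L,
                              start_year = 2010L, end_year = 2040L) {
  if (n_runs < 1) stop_arg("n_runs must be >= 1")
  if (!length(scenarios)) stop_arg("scenario set must be non-empty")
  scenarios <- match.arg(scenarios, c("rcp26", "rcp45", "rcp85"), several.ok = TRUE)
  if (m_range[1] < 0.5 || m_range[2] > 1.5) {
    stop_arg("m_range must lie within [0.5, 1.5]")
  }
  if (credit_range[1] < 0 || credit_range[2] > 2) {
    stop_arg("credit_range must lie within [0, 2]")
  }
  structure(
    list(
      n_runs = as.integer(n_runs), scenarios = scenarios,
      m_range = m_range, credit_range = credit_range,
      other_ranges = other_ranges, seed_base = as.integer(seed_base),
      n_agents = as.integer(n_agents),
      start_year = as.integer(start_year), end_year = as.integer(end_year)
    ),
    class = c("experiment_design", "list")
  )
}

#' Run a Monte Carlo ensemble of simulations
#'
#' Executes `design$n_runs` simulations with independently drawn parameters
#' and per-run seeds, and collects one outcome row per run: every drawn
#' parameter plus normalized net coastal migration, migrant and move counts,
#' mean final wealth, overall moored share, and the moored cohort's mean
#' wealth, CRRA and prior-move count.
#'
#' @param design an [experiment_design()].
#' @param world a world (shared across runs; populations are regenerated per
#'   run).
#' @param keep_results also return the full per-run `sim_result` objects.
#' @return An `OutcomeTable` data frame (one row per run), with the run
#'   results in `attr(, "results")` when requested.
#' @export
run_experiment <- function(design, world, keep_results = FALSE) {
  rows <- vector("list", design$n_runs)
  results <- if (keep_results) vector("list", design$n_runs) else NULL
  orng <- design$other_ranges
  for (r in seq_len(design$n_runs)) {
    seed <- design$seed_base + r
    draws <- with_seed((seed * 7919 + 104729) %% 2147483647, {
      list(
        scenario = design$scenarios[sample.int(length(design$scenarios), 1L)],
        m = runif(1, design$m_range[1], design$m_range[2]),
        credit_multiplier = runif(1, design$credit_range[1], design$credit_range[2]),
        k_locations = round(runif(1, orng$k_locations[1], orng$k_locations[2])),
        rho_scale = runif(1, orng$rho_scale[1], orng$rho_scale[2]),
        info_share_prob = runif(1, orng$info_share_prob[1], orng$info_share_prob[2]),
        p_reconsider_mean = runif(1, orng$p_reconsider_mean[1], orng$p_reconsider_mean[2])
      )
    })
    res <- run_simulation(
      world,
      scenario = flood_scenario(draws$scenario,
        m = draws$m,
        start_year = design$start_year, end_year = design$end_year
      ),
      start_year = design$start_year, end_year = design$end_year,
      seed = seed, n_agents = design$n_agents,
      point = draws[c(
        "credit_multiplier", "k_locations", "rho_scale",
        "info_share_prob", "p_reconsider_mean"
      )],
      record_histories = FALSE
    )
    moored <- moored_cohort_stats(res$state$pop, res$state$schedules$adult_age)
    s <- res$summary
    rows[[r]] <- data.frame(
      run = r, seed = seed,
      scenario = draws$scenario,
      slr_end = flood_scenario(draws$scenario)$slr_end,
      m = draws$m,
      credit_multiplier = draws$credit_multiplier,
      k_locations = draws$k_locations,
      rho_scale = draws$rho_scale,
      info_share_prob = draws$info_share_prob,
      p_reconsider_mean = draws$p_reconsider_mean,
      net_coastal_migration = s$net_coastal_migration,
      total_migrations = s$total_migrations,
      total_moves = s$total_moves,
      mean_final_wealth = s$mean_final_wealth,
      moored_share = s$moored_share,
      moored_mean_wealth = moored$mean_wealth,
      moored_mean_crra = moored$mean_crra,
      moored_mean_prior_moves = moored$mean_prior_moves,
      final_population = s$final_population
    )
    if (keep_results) results[[r]] <- res
  }
  out <- do.call(rbind, rows)
  if (keep_results) attr(out, "results") <- results
  out
}

moored_cohort_stats <- function(pop, adult_age) {
  n <- pop$n
  idx <- which(pop$alive[seq_len(n)] & pop$age[seq_len(n)] >= adult_age &
    pop$moored[seq_len(n)])
  if (!length(idx)) {
    return(list(
      mean_wealth = NA_real_, mean_crra = NA_real_,
      mean_prior_moves = NA_real_
    ))
  }
  list(
    mean_wealth = mean(pop$wealth[idx]),
    mean_crra = mean(pop$rho[idx]),
    mean_prior_moves = mean(pop$moves_at_moor[idx], na.rm = TRUE)
  )
}

#' Normalized net migration by district
#'
#' For each district, in-flow minus out-flow (column sum minus row sum of the
#' flow matrix) divided by the total agent population; entries sum to zero.
#'
#' @param flows a [flow_matrix()].
#' @param total_population positive agent count used for normalization.
#' @export
net_migration_by_district <- function(flows, total_population) {
  if (total_population <= 0) stop_arg("total_population must be positive")
  (colSums(flows) - rowSums(flows)) / total_population
}

#' Largest inter-district flows
#'
#' Returns the `ceiling(fraction * D * (D - 1))` largest off-diagonal cells in
#' descending order, ties broken by origin then destination id.
#'
#' @param flows a [flow_matrix()].
#' @param fraction proportion of off-diagonal cells to return, in `(0, 1]`.
#' @return data frame with `origin`, `destination`, `count`.
#' @export
top_flows <- function(flows, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop_arg("fraction must lie in (0, 1]")
  D <- nrow(flows)
  idx <- which(row(flows) != col(flows))
  k <- ceiling(fraction * D * (D - 1L))
  o <- row(flows)[idx]
  d <- col(flows)[idx]
  cnt <- as.numeric(flows[idx])
  ord <- order(-cnt, o, d)
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(origin = o[sel], destination = d[sel], count = cnt[sel])
}

#' Moored-population analysis of a finished run
#'
#' The moored share is the fraction of alive adult agents whose current
#' moored flag is set (their latest reconsideration found a strictly better
#' but unaffordable option), per district and overall. Cohort covariates are
#' means over moored agents: wealth, CRRA, and moves made strictly before the
#' first moored event. Covariates are `NA` (and `n_moored = 0`) when nobody
#' is moored.
#'
#' @param result a `sim_result` from [run_simulation()].
#' @return list with `overall_share`, `share_by_district`, `n_moored`, and
#'   the cohort covariate means.
#' @export
moored_analysis <- function(result) {
  st <- result$state
  pop <- st$pop
  n <- pop$n
  adult <- which(pop$alive[seq_len(n)] & pop$age[seq_len(n)] >= st$schedules$adult_age)
  D <- nrow(st$world$districts)
  tot <- tabulate(pop$district[adult], D)
  moo <- tabulate(pop$district[adult][pop$moored[adult]], D)
  stats <- moored_cohort_stats(pop, st$schedules$adult_age)
  list(
    overall_share = if (length(adult)) mean(pop$moored[adult]) else NA_real_,
    share_by_district = ifelse(tot > 0, moo / tot, NA_real_),
    n_moored = sum(moo),
    mean_wealth = stats$mean_wealth,
    mean_crra = stats$mean_crra,
    mean_prior_moves = stats$mean_prior_moves
  )
}

#' Coastal versus interior correlation of in-migration and mooring
#'
#' Spearman rank correlation between per-district net in-migration and moored
#' share, computed separately within the coastal and the interior stratum.
#' Strata with fewer than three districts yield a flagged `NA` rather than an
#' error.
#'
#' @param net_mig per-district normalized net migration.
#' @param moored_share per-district moored share.
#' @param coastal logical vector of coastal flags.
#' @return data frame with one row per stratum: `stratum`, `rho`, `n`, `ok`.
#' @export
coastal_interior_correlation <- function(net_mig, moored_share, coastal) {
  one <- function(sel, label) {
    keep <- sel & !is.na(net_mig) & !is.na(moored_share)
    n <- sum(keep)
    rho <- if (n >= 3) {
      suppressWarnings(cor(net_mig[keep], moored_share[keep], method = "spearman"))
    } else {
      NA_real_
    }
    data.frame(stratum = label, rho = rho, n = n, ok = n >= 3)
  }
  rbind(one(coastal, "coastal"), one(!coastal, "interior"))
}

#' Random-forest permutation importance of experiment parameters
#'
#' Fits an ensemble-of-trees regressor of the target outcome on the drawn
#' parameter columns and scores each parameter by permutation importance: the
#' mean decrease in held-out R-squared over `n_perm` permutations of that
#' column, on a 30% held-out split. Deterministic given `seed`.
#'
#' @param outcomes an OutcomeTable from [run_experiment()] (or any data
#'   frame).
#' @param target name of the outcome column.
#' @param parameters character vector of parameter column names.
#' @param n_perm permutations per parameter.
#' @param seed RNG seed.
#' @param min_rows minimum rows required.
#' @return data frame sorted by decreasing `importance`.
#' @export
parameter_importance <- function(outcomes, target,
                                 parameters = c(
                                   "slr_end", "m", "credit_multiplier",
                                   "k_locations", "rho_scale",
                                   "info_share_prob", "p_reconsider_mean"
                                 ),
                                 n_perm = 20L, seed = 1L, min_rows = 30L) {
  parameters <- intersect(parameters, names(outcomes))
  if (!target %in% names(outcomes)) stop_arg("target column not present")
  df <- outcomes[stats::complete.cases(outcomes[c(target, parameters)]),
    c(target, parameters),
    drop = FALSE
  ]
  if (nrow(df) < min_rows) stop_arg("need at least ", min_rows, " complete rows")
  with_seed(seed, {
    n <- nrow(df)
    test <- sample.int(n, max(5L, floor(0.3 * n)))
    train <- setdiff(seq_len(n), test)
    fml <- stats::reformulate(parameters, response = target)
    fit <- ranger::ranger(fml,
      data = df[train, ], num.trees = 500L,
      seed = 1L, num.threads = 1L
    )
    base_r2 <- heldout_r2(fit, df[test, ], target)
    imp <- vapply(parameters, function(p) {
      mean(vapply(seq_len(n_perm), function(k) {
        perm <- df[test, ]
        perm[[p]] <- perm[[p]][sample.int(nrow(perm))]
        base_r2 - heldout_r2(fit, perm, target)
      }, numeric(1)))
    }, numeric(1))
    out <- data.frame(parameter = parameters, importance = imp)
    out[order(-out$importance), ]
  })
}

heldout_r2 <- function(fit, newdata, target) {
  pred <- predict(fit, data = newdata, num.threads = 1L)$predictions
  y <- newdata[[target]]
  ss <- sum((y - mean(y))^2)
  if (ss == 0) return(0)
  1 - sum((y - pred)^2) / ss
}
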