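# Shared fixtures, built in code.

# Calibrated default parameter set, computed once per test run.
calibrated_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate_natural_history(default_parameters())
    }
    cache
  }
})

# Published base-case per-strategy cost and life-year values, used as the
# worked example for the incremental analysis.
published_pairs <- function() {
  data.frame(
    strategy = c("NH", "FIT", "Colonoscopy", "S-DNA", "C-LB", "LB"),
    cost = c(6284, 8223, 9037, 11583, 12006, 15562),
    effectiveness = c(35.574, 35.624, 35.672, 35.641, 35.680, 35.581)
  )
}

# Independent brute-force frontier oracle: gift-wrapping construction of the
# efficiency frontier (repeatedly pick the minimum-ICER move among all
# more-effective strategies), plus exhaustive pairwise strict-dominance
# checks. Deliberately a different algorithm from the package's iterative
# removal implementation.
oracle_frontier_status <- function(pairs) {
  n <- nrow(pairs)
  strict <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n)[-i], function(j) {
      pairs$cost[j] <= pairs$cost[i] &&
        pairs$effectiveness[j] >= pairs$effectiveness[i] &&
        (pairs$cost[j] < pairs$cost[i] ||
           pairs$effectiveness[j] > pairs$effectiveness[i])
    }, TRUE))
  }, TRUE)
  on_hull <- rep(FALSE, n)
  cur <- which(!strict)[which.min(pairs$cost[!strict])]
  cur <- which(pairs$cost == min(pairs$cost[!strict]) & !strict)[1]
  on_hull[cur] <- TRUE
  repeat {
    cand <- which(pairs$effectiveness > pairs$effectiveness[cur])
    if (length(cand) == 0) break
    icers <- (pairs$cost[cand] - pairs$cost[cur]) /
      (pairs$effectiveness[cand] - pairs$effectiveness[cur])
    cur <- cand[which.min(icers)]
    on_hull[cur] <- TRUE
  }
  status <- ifelse(strict, "strictly_dominated",
                   ifelse(on_hull, "nondominated", "extendedly_dominated"))
  status[on_hull & pairs$cost == min(pairs$cost[on_hull])] <- "reference"
  status
}

# Random frontier instance without ties (ties have a documented
# deterministic rule tested separately).
random_pairs <- function(n) {
  data.frame(strategy = paste0("S", seq_len(n)),
             cost = round(runif(n, 100, 10000), 4),
             effectiveness = round(runif(n, 10, 40), 6))
}
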