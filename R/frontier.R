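#' Incremental cost-effectiveness analysis with dominance
#'
#' Sorts strategies by cost, removes strictly dominated strategies (cost at
#' least as high as another's with no more effectiveness; exact ties are
#' dominated, broken deterministically by name order), then repeatedly
#' removes extendedly dominated strategies (whose ICER against the previous
#' survivor exceeds the ICER of the next survivor against them) until ICERs
#' along the frontier are non-decreasing. Every non-reference strategy is
#' reported against the most expensive nondominated strategy cheaper than
#' itself, matching the convention that the ICER is computed relative to
#' the next least costly nondominated strategy.
#'
#' @param pairs Data frame with columns `strategy` (unique names), `cost`
#'   and `effectiveness` (finite numbers), or a list of such triples.
#' @return A data frame of class `frontier_result`: one row per strategy
#'   with `status` (`reference` / `nondominated` / `strictly_dominated` /
#'   `extendedly_dominated`), `incremental_cost`, `incremental_effect`,
#'   `comparator`, and `icer` (NA for the reference and for dominated
#'   strategies).
#' @export
incremental_analysis <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(strategy = p[[1]], cost = as.numeric(p[[2]]),
                 effectiveness = as.numeric(p[[3]]))
    }))
  }
  if (!is.data.frame(pairs) || nrow(pairs) < 1 ||
      !all(c("strategy", "cost", "effectiveness") %in% names(pairs))) {
    stop("incremental_analysis: need at least one (strategy, cost, effectiveness) triple")
  }
  if (anyDuplicated(pairs$strategy)) {
    stop("incremental_analysis: duplicate strategy names")
  }
  if (!all(is.finite(pairs$cost)) || !all(is.finite(pairs$effectiveness))) {
    stop("incremental_analysis: costs and effects must be finite")
  }

  d <- pairs[order(pairs$cost, pairs$effectiveness, pairs$strategy), ]
  d$status <- "nondominated"

  # strict dominance: some other strategy has cost <= and effect >= with at
  # least one strict (ties dominated deterministically by the sort order)
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i == j) next
      ci <- d$cost[i]; cj <- d$cost[j]
      ei <- d$effectiveness[i]; ej <- d$effectiveness[j]
      tie <- ci == cj && ei == ej
      if ((cj <= ci && ej >= ei && !tie) || (tie && j < i)) {
        d$status[i] <- "strictly_dominated"
        break
      }
    }
  }

  # extended dominance on the surviving chain
  repeat {
    chain <- which(d$status == "nondominated")
    if (length(chain) < 3) break
    removed <- FALSE
    for (k in 2:(length(chain) - 1)) {
      lo <- chain[k - 1]; mid <- chain[k]; hi <- chain[k + 1]
      icer_mid <- (d$cost[mid] - d$cost[lo]) /
        (d$effectiveness[mid] - d$effectiveness[lo])
      icer_hi <- (d$cost[hi] - d$cost[mid]) /
        (d$effectiveness[hi] - d$effectiveness[mid])
      if (icer_mid > icer_hi) {
        d$status[mid] <- "extendedly_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  chain <- which(d$status == "nondominated")
  d$status[chain[1]] <- "reference"
  d$incremental_cost <- NA_real_
  d$incremental_effect <- NA_real_
  d$comparator <- NA_character_
  d$icer <- NA_real_
  nondom <- which(d$status %in% c("reference", "nondominated"))
  for (i in seq_len(nrow(d))[-chain[1]]) {
    below <- nondom[d$cost[nondom] < d$cost[i] |
                      (d$cost[nondom] == d$cost[i] & nondom < i)]
    if (length(below) == 0) next
    cmp <- below[length(below)]
    d$incremental_cost[i] <- d$cost[i] - d$cost[cmp]
    d$incremental_effect[i] <- d$effectiveness[i] - d$effectiveness[cmp]
    d$comparator[i] <- d$strategy[cmp]
    if (d$status[i] == "nondominated") {
      d$icer[i] <- d$incremental_cost[i] / d$incremental_effect[i]
    }
  }
  rownames(d) <- NULL
  class(d) <- c("frontier_result", "data.frame")
  d
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("<frontier_result> incremental cost-effectiveness analysis\n")
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Pick the cost-effective strategy at a willingness-to-pay threshold
#'
#' The most effective nondominated strategy whose ICER does not exceed the
#' willingness-to-pay; the reference (least costly nondominated) strategy
#' if none qualifies.
#'
#' @param frontier A [incremental_analysis()] result.
#' @param wtp Willingness-to-pay threshold in USD per life-year gained.
#' @return The chosen strategy name.
#' @export
decide_cost_effective <- function(frontier, wtp) {
  stopifnot(inherits(frontier, "frontier_result"), wtp >= 0)
  ref <- frontier$strategy[frontier$status == "reference"]
  ok <- frontier$status == "nondominated" & frontier$icer <= wtp
  if (!any(ok)) return(ref)
  cand <- frontier[ok, ]
  cand$strategy[which.max(cand$effectiveness)]
}
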