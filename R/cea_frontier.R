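# Incremental analysis: pairwise ICERs, strict and extended dominance, the
# cost-effectiveness frontier with sequential ICERs, and net monetary benefit.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computes \code{(cost_a - cost_b) / (qaly_a - qaly_b)} and classifies the
#' comparison: \code{"ratio"} for a genuine trade-off, \code{"dominant"} when
#' a is no more costly and no less effective than b (strictly better on one
#' axis), \code{"dominated"} for the reverse, and \code{"degenerate"} when
#' the QALY difference is exactly zero (no ratio is defined; \code{value} is
#' NA).
#'
#' @param a,b Lists or one-row data frames with \code{cost} and \code{qaly}.
#' @return List with \code{value} (the ratio, NA when degenerate) and
#'   \code{status}.
#' @export
icer <- function(a, b) {
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  if (dq == 0) {
    return(list(value = NA_real_, status = "degenerate"))
  }
  status <- if (dc <= 0 && dq >= 0) "dominant"
  else if (dc >= 0 && dq <= 0) "dominated"
  else "ratio"
  list(value = dc / dq, status = status)
}

#' Net monetary benefit
#'
#' \code{threshold * qaly - cost}; the strategy maximising NMB is
#' cost-effective at that willingness-to-pay threshold.
#'
#' @param result List or data frame with \code{cost} and \code{qaly}
#'   (vectorised over rows).
#' @param threshold Willingness-to-pay threshold (currency per QALY), >= 0.
#' @return Numeric NMB.
#' @export
nmb <- function(result, threshold) {
  if (any(threshold < 0)) stop("nmb: threshold must be >= 0", call. = FALSE)
  threshold * result$qaly - result$cost
}

#' Construct the cost-effectiveness frontier
#'
#' Sorts strategies by ascending cost, removes strictly dominated strategies
#' (another strategy no worse on both axes and strictly better on at least
#' one; exact ties keep the first by input order), then iteratively removes
#' extended-dominated strategies until the sequential ICERs along the
#' frontier are strictly increasing.
#'
#' @param results Data frame with columns \code{arm}, \code{cost},
#'   \code{qaly} (e.g. from \code{run_all}).
#' @return A \code{frontier_result} data frame in ascending cost order with
#'   columns \code{arm}, \code{cost}, \code{qaly}, \code{classification}
#'   (\code{on_frontier} / \code{dominated} / \code{extended_dominated}) and
#'   \code{seq_icer} (ICER versus the next-cheaper frontier strategy; NA for
#'   the cheapest and for excluded strategies).
#' @export
build_frontier <- function(results) {
  stopifnot(is.data.frame(results), all(c("arm", "cost", "qaly") %in% names(results)))
  n <- nrow(results)
  if (!n) stop("build_frontier: empty results", call. = FALSE)
  df <- data.frame(arm = as.character(results$arm), cost = results$cost,
                   qaly = results$qaly, input_order = seq_len(n),
                   stringsAsFactors = FALSE)

  classification <- rep("on_frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better_or_equal <- df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i]
      strictly <- df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i]
      tie <- df$cost[j] == df$cost[i] && df$qaly[j] == df$qaly[i]
      if (better_or_equal && (strictly || (tie && j < i))) {
        classification[i] <- "dominated"
        break
      }
    }
  }

  cand <- which(classification == "on_frontier")
  cand <- cand[order(df$cost[cand], df$qaly[cand], df$input_order[cand])]
  # iteratively drop any strategy whose ICER vs the previous retained one
  # exceeds the ICER of the next retained one (extended dominance); exactly
  # collinear points are kept
  repeat {
    if (length(cand) < 3L) break
    ic <- diff(df$cost[cand]) / diff(df$qaly[cand])
    bad <- which(ic[-length(ic)] > ic[-1])
    if (!length(bad)) break
    classification[cand[bad[1] + 1L]] <- "extended_dominated"
    cand <- cand[-(bad[1] + 1L)]
  }

  seq_icer <- rep(NA_real_, n)
  if (length(cand) > 1L) {
    seq_icer[cand[-1]] <- diff(df$cost[cand]) / diff(df$qaly[cand])
  }
  out <- df[order(df$cost, df$qaly, df$input_order),
            c("arm", "cost", "qaly")]
  out$classification <- classification[order(df$cost, df$qaly, df$input_order)]
  out$seq_icer <- seq_icer[order(df$cost, df$qaly, df$input_order)]
  rownames(out) <- NULL
  class(out) <- c("frontier_result", "data.frame")
  out
}

#' Arms on the cost-effectiveness frontier
#' @param frontier A \code{frontier_result}.
#' @return Character vector of arm names, ascending cost.
#' @export
frontier_arms <- function(frontier) {
  frontier$arm[frontier$classification == "on_frontier"]
}

#' ICER table versus a reference strategy
#'
#' Reproduces the "ICER compared with reference" column of a base-case
#' results table.
#'
#' @param results Data frame with \code{arm}, \code{cost}, \code{qaly}.
#' @param reference Name of the reference arm.
#' @return Data frame with \code{arm}, \code{icer_vs_ref}, \code{status}.
#' @export
icer_table <- function(results, reference) {
  i <- match(reference, results$arm)
  if (is.na(i)) stop("icer_table: no arm named '", reference, "'", call. = FALSE)
  ref <- results[i, ]
  rows <- lapply(seq_len(nrow(results)), function(j) {
    if (j == i) {
      return(data.frame(arm = results$arm[j], icer_vs_ref = NA_real_,
                        status = "reference", stringsAsFactors = FALSE))
    }
    ic <- icer(results[j, ], ref)
    data.frame(arm = results$arm[j], icer_vs_ref = ic$value, status = ic$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
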