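#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative,
#' with ties counting one half -- computed from the Mann-Whitney rank
#' statistic.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same cases using the
#' paired DeLong variance of the placement values: for each positive,
#' its placement is the fraction of negatives it outscores (ties half);
#' symmetrically for negatives.  The AUC difference divided by its
#' estimated standard error is referred to the standard normal
#' (two-sided).
#'
#' @param scores_a,scores_b Paired score vectors over identical cases.
#' @param labels Logical or 0/1 labels.
#' @return list(auc_a, auc_b, p).  When the estimated variance of the
#'   difference is zero (e.g. identical scores) p is 1.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")

  placements <- function(s) {
    pos <- s[labels]; neg <- s[!labels]
    v10 <- vapply(pos, function(x)
      mean((x > neg) + 0.5 * (x == neg)), numeric(1))
    v01 <- vapply(neg, function(x)
      mean((pos > x) + 0.5 * (pos == x)), numeric(1))
    list(v10 = v10, v01 = v01)
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)

  n1 <- sum(labels); n0 <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  p <- if (var_diff <= 0) 1 else
    2 * stats::pnorm(-abs(auc_a - auc_b) / sqrt(var_diff))
  list(auc_a = auc_a, auc_b = auc_b, p = min(p, 1))
}

#' Fisher's exact test on a 2x2 table
#'
#' Sample odds ratio `(a*d)/(b*c)` with the Haldane correction (+0.5 to
#' every cell) if and only if some cell is zero, and the two-sided exact
#' p-value obtained by summing all hypergeometric outcomes (at the
#' observed margins) whose probability does not exceed that of the
#' observed table (minimum-likelihood convention).
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows
#'   (group 1: a, b) and (group 2: c, d).
#' @return list(odds_ratio, p).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (a + b == 0 || c + d == 0) stop("a margin of the table is empty")
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  m <- a + c          # column-1 total
  n <- b + d          # column-2 total
  k <- a + b          # row-1 total
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1))
}

#' Rank-interval enrichment table
#'
#' Cuts a ranked gene list into `B` near-equal intervals (sizes differ
#' by at most 1; the larger intervals sit at the bottom of the ranking,
#' so the top interval holds `floor(n / B)` genes) and, per interval,
#' tests the association between interval membership and membership in
#' an evidence gene set with [fisher_2x2()].
#'
#' @param ranking Character vector of genes ordered best-first.  Ties
#'   must already be resolved (input order is the ranking).
#' @param evidence Character vector of evidence genes, a subset of
#'   `ranking`.
#' @param B Number of intervals (default 20).
#' @return An `enrichment_table` data.frame: interval, lower_pct,
#'   upper_pct, n_genes, n_with_evidence, odds_ratio, p_value.
#' @export
rank_interval_enrichment <- function(ranking, evidence, B = 20L) {
  n <- length(ranking)
  B <- as.integer(B)
  if (B > n) stop("more intervals than genes")
  if (anyDuplicated(ranking)) stop("ranking contains duplicate genes")
  extra <- setdiff(evidence, ranking)
  if (length(extra))
    stop("evidence genes outside the ranking universe: ",
         paste(utils::head(extra, 3), collapse = ", "))
  sizes <- rep(n %/% B, B)
  rem <- n %% B
  if (rem) sizes[(B - rem + 1L):B] <- sizes[(B - rem + 1L):B] + 1L
  stop_at <- cumsum(sizes)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  n_evid <- length(unique(evidence))
  rows <- lapply(seq_len(B), function(i) {
    in_int <- ranking[start_at[i]:stop_at[i]]
    a <- sum(in_int %in% evidence)
    b <- length(in_int) - a
    cc <- n_evid - a
    d <- n - length(in_int) - cc
    ft <- fisher_2x2(a, b, cc, d)
    data.frame(interval = i,
               lower_pct = 100 * (start_at[i] - 1L) / n,
               upper_pct = 100 * stop_at[i] / n,
               n_genes = length(in_int), n_with_evidence = a,
               odds_ratio = ft$odds_ratio, p_value = ft$p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Cumulative evidence distribution over rank intervals
#'
#' For each of `B` rank intervals, the cumulative fraction of all
#' evidence genes found at or above that interval; non-decreasing and
#' ending at 1.
#'
#' @inheritParams rank_interval_enrichment
#' @return Numeric vector of length `B`.
#' @export
evidence_cdf <- function(ranking, evidence, B = 20L) {
  if (!length(evidence)) stop("evidence set is empty")
  tab <- rank_interval_enrichment(ranking, evidence, B)
  cumsum(tab$n_with_evidence) / sum(tab$n_with_evidence)
}

#' Stepwise hypergeometric enrichment curve
#'
#' At each cutoff k = step, 2*step, ..., N, computes the upper-tail
#' hypergeometric probability of drawing at least the observed overlap
#' between the top-k genes and a reference set, in k draws from the
#' universe.  The enriched-region AUC summarises the curve: the
#' -log10(p) values are masked to the region p < 0.05 and summed as a
#' Riemann area over the cutoff fractions k / N
#' (`sum(-log10(p) * step / N)` over enriched cutoffs).
#'
#' @param ranking Character vector of genes ordered best-first.
#' @param reference Character vector of reference genes (subset of the
#'   universe).
#' @param step Cutoff increment in genes (default 50); the final cutoff
#'   N is always included.
#' @return An object of class `"stepwise_curve"`: data.frame `curve`
#'   (cutoff, overlap, p) and scalar `auc`.
#' @export
stepwise_hypergeom <- function(ranking, reference, step = 50L) {
  step <- as.integer(step)
  stopifnot(step >= 1L)
  n <- length(ranking)
  extra <- setdiff(reference, ranking)
  if (length(extra))
    stop("reference genes outside the ranking universe: ",
         paste(utils::head(extra, 3), collapse = ", "))
  K <- length(unique(reference))
  cutoffs <- unique(c(seq(step, n, by = step), n))
  in_ref <- ranking %in% reference
  cum_overlap <- cumsum(in_ref)
  overlap <- cum_overlap[cutoffs]
  p <- stats::phyper(overlap - 1L, K, n - K, cutoffs, lower.tail = FALSE)
  widths <- diff(c(0L, cutoffs)) / n
  y <- ifelse(p < 0.05, -log10(p), 0)
  structure(list(curve = data.frame(cutoff = cutoffs, overlap = overlap,
                                    p = p),
                 auc = sum(y * widths)),
            class = "stepwise_curve")
}

#' @export
print.stepwise_curve <- function(x, ...) {
  enr <- sum(x$curve$p < 0.05)
  cat(sprintf(
    "stepwise_curve: %d cutoffs, %d enriched (p < 0.05), enriched-region AUC %.4g\n",
    nrow(x$curve), enr, x$auc))
  invisible(x)
}
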