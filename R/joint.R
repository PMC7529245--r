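#' Joint RNA x H3K9me2 direction classification
#'
#' Restricts to the features called significant (non-`ns`) in both assays and
#' cross-tabulates the direction of the transcript change against the
#' direction of the H3K9me2 change, the four-quadrant view of how chromatin
#' and expression move together.
#'
#' @param rna_results,k9_results `diff_result` data frames over a shared
#'   feature universe
#' @return list: `features` (feature, rna_call, k9_call for the doubly
#'   significant set), `quadrants` (2x2 integer matrix, rows = RNA up/down,
#'   cols = K9 up/down), `n_both`
#' @export
classify_joint <- function(rna_results, k9_results) {
  shared <- intersect(rna_results$feature, k9_results$feature)
  if (length(shared) == 0L)
    stop("RNA and K9 results share no feature ids")
  r <- rna_results[match(shared, rna_results$feature), ]
  k <- k9_results[match(shared, k9_results$feature), ]
  both <- r$call != "ns" & k$call != "ns"
  feats <- data.frame(feature = shared[both],
                      rna_call = r$call[both], k9_call = k$call[both],
                      stringsAsFactors = FALSE)
  quad <- matrix(0L, 2, 2,
                 dimnames = list(rna = c("up", "down"), k9 = c("up", "down")))
  for (rn in c("up", "down")) for (kn in c("up", "down"))
    quad[rn, kn] <- sum(feats$rna_call == rn & feats$k9_call == kn)
  list(features = feats, quadrants = quad, n_both = nrow(feats))
}

#' Chi-square balance test against an equal up/down split
#'
#' One-degree-of-freedom goodness-of-fit test of the observed (up, down)
#' counts against the expected equal split (n/2, n/2), no continuity
#' correction. For this 2-cell table the statistic reduces to
#' `(up - down)^2 / n`.
#'
#' @param up_count,down_count non-negative counts, not both zero
#' @return list: `chisq`, `p`, `n`
#' @examples
#' balance_chi_square(40, 11)  # chisq 16.49, p < 0.001
#' @export
balance_chi_square <- function(up_count, down_count) {
  n <- up_count + down_count
  if (n < 1) stop("up_count + down_count must be >= 1")
  chisq <- (up_count - down_count)^2 / n
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = n)
}

#' Integer percentage split of up vs down counts
#'
#' Percent up is rounded to the nearest integer, ties away from zero;
#' percent down is its complement so the two always sum to 100.
#'
#' @inheritParams balance_chi_square
#' @return list: `percent_up`, `percent_down`
#' @examples
#' proportion_summary(2532, 1976)  # 56 / 44
#' @export
proportion_summary <- function(up_count, down_count) {
  n <- up_count + down_count
  if (n < 1) stop("up_count + down_count must be >= 1")
  pct_up <- floor(100 * up_count / n + 0.5)
  list(percent_up = pct_up, percent_down = 100 - pct_up)
}

#' Up/down balance per functional category
#'
#' For each category label attached to the features of a differential
#' result, counts up- and down-called features, their percentage split, and
#' the equal-split chi-square test.
#'
#' @param diff_res a `diff_result` data frame
#' @param categories data frame with columns `feature`, `category` (one row
#'   per label; features may carry several labels)
#' @return data frame: `category`, `up`, `down`, `percent_up`,
#'   `percent_down`, `chisq`, `p`
#' @export
category_balance <- function(diff_res, categories) {
  calls <- diff_res$call[match(categories$feature, diff_res$feature)]
  out <- lapply(unique(categories$category), function(cat) {
    sel <- categories$category == cat
    up <- sum(calls[sel] == "up", na.rm = TRUE)
    down <- sum(calls[sel] == "down", na.rm = TRUE)
    if (up + down == 0)
      return(data.frame(category = cat, up = 0L, down = 0L,
                        percent_up = NA_real_, percent_down = NA_real_,
                        chisq = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    pr <- proportion_summary(up, down)
    bc <- balance_chi_square(up, down)
    data.frame(category = cat, up = up, down = down,
               percent_up = pr$percent_up, percent_down = pr$percent_down,
               chisq = bc$chisq, p = bc$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
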