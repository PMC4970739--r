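#' Diagnostic test performance
#'
#' @param sensitivity,specificity,p_unknown probabilities in [0, 1].
#'   `p_unknown` is the proportion of specimens where the assay cannot
#'   determine mutation status (inadequate tumor tissue).
#' @return An object of class `test_performance`.
#' @export
test_performance <- function(sensitivity, specificity, p_unknown = 0) {
  for (nm in c("sensitivity", "specificity", "p_unknown")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 p_unknown = p_unknown),
            class = "test_performance")
}

#' Decision-tree branch proportions for a test-and-treat strategy
#'
#' Splits the tested cohort into true/false positives and negatives plus
#' unknown results. Determinate results occur with probability
#' (1 - p_unknown), then classify by mutation status and test accuracy:
#' \deqn{pTP = prev \cdot sens \cdot (1 - pU)}
#' \deqn{pFP = (1 - prev)(1 - spec)(1 - pU)}
#' \deqn{pTN = (1 - prev) \cdot spec \cdot (1 - pU)}
#' \deqn{pFN = prev (1 - sens)(1 - pU)}
#' The five proportions sum to one. Patients with a positive test result
#' (true or false) follow the targeted-therapy pathway; negative and
#' unknown results follow the chemotherapy pathway.
#'
#' @param prevalence proportion of the cohort harboring the mutation.
#' @param perf a [test_performance()].
#' @return An object of class `branch_proportions`: a list with `p_tp`,
#'   `p_fp`, `p_tn`, `p_fn`, `p_unknown`, and derived `p_test_positive`
#'   (= p_tp + p_fp) and `p_test_negative` (= p_tn + p_fn).
#' @examples
#' bp <- branch_proportions(0.39, test_performance(0.984, 0.892, 0.11))
#' bp$p_test_positive  # about 0.4002
#' @export
branch_proportions <- function(prevalence, perf) {
  if (length(prevalence) != 1L || !is.finite(prevalence) ||
      prevalence < 0 || prevalence > 1) {
    stop("`prevalence` must be a probability in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(perf, "test_performance"))
  det <- 1 - perf$p_unknown
  out <- list(
    p_tp = prevalence * perf$sensitivity * det,
    p_fp = (1 - prevalence) * (1 - perf$specificity) * det,
    p_tn = (1 - prevalence) * perf$specificity * det,
    p_fn = prevalence * (1 - perf$sensitivity) * det,
    p_unknown = perf$p_unknown
  )
  out$p_test_positive <- out$p_tp + out$p_fp
  out$p_test_negative <- out$p_tn + out$p_fn
  total <- out$p_test_positive + out$p_test_negative + out$p_unknown
  stopifnot(abs(total - 1) < 1e-12)
  structure(out, class = "branch_proportions")
}

#' @export
print.branch_proportions <- function(x, ...) {
  cat("<branch_proportions>\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.branch_proportions <- function(x, ...) {
  data.frame(
    branch = c("true_positive", "false_positive", "true_negative",
               "false_negative", "unknown"),
    proportion = c(x$p_tp, x$p_fp, x$p_tn, x$p_fn, x$p_unknown)
  )
}
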