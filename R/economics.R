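#' Pairwise cost-effectiveness comparison
#'
#' Computes incremental cost and effect of an intervention over a
#' comparator and labels the result: `"dominant"` when the intervention is
#' cheaper and more effective, `"dominated"` when it is costlier and less
#' effective, `"undefined ICER"` when the incremental effect is zero, and
#' otherwise the ICER (incremental cost / incremental effect, USD per
#' QALY).
#'
#' @param intervention,comparator [ce_result()] objects.
#' @return An object of class `ce_comparison` with fields `incr_cost`,
#'   `incr_effect`, `icer` (`NA` when not defined) and `verdict`.
#' @examples
#' a <- ce_result("test", 21528, 0.64013)
#' b <- ce_result("no test", 19954, 0.55591)
#' compare_strategies(a, b)  # ICER about 18,690 USD/QALY
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "ce_result"), inherits(comparator, "ce_result"))
  dc <- intervention$cost - comparator$cost
  de <- intervention$effect - comparator$effect
  if (de == 0) {
    verdict <- "undefined ICER"
    icer <- NA_real_
  } else if (dc < 0 && de > 0) {
    verdict <- "dominant"
    icer <- NA_real_
  } else if (dc > 0 && de < 0) {
    verdict <- "dominated"
    icer <- NA_real_
  } else {
    icer <- dc / de
    verdict <- sprintf("ICER %.0f", icer)
  }
  structure(
    list(intervention = intervention$strategy, comparator = comparator$strategy,
         incr_cost = dc, incr_effect = de, icer = icer, verdict = verdict),
    class = "ce_comparison"
  )
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("<ce_comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost:   $%s\n", format(round(x$incr_cost), big.mark = ",")))
  cat(sprintf("  incremental effect: %.5f QALY\n", x$incr_effect))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' iNMB = wtp x incremental effect - incremental cost. Positive values
#' favor the intervention at the given willingness-to-pay threshold. Used
#' as the tornado summary when the base case is dominant (the ICER is then
#' undefined or sign-ambiguous).
#'
#' @param comparison a [compare_strategies()] result.
#' @param wtp willingness-to-pay threshold (USD per QALY).
#' @return numeric iNMB in USD.
#' @export
inmb <- function(comparison, wtp) {
  wtp * comparison$incr_effect - comparison$incr_cost
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates a model at the low and high value of each parameter in
#' turn, holding everything else at base case, and reports the swing in a
#' summary statistic. Entries are sorted by descending bar width. A model
#' failure at an endpoint flags the entry (`error` column) and the analysis
#' continues.
#'
#' @param eval_fn function of `(name, value)` returning a
#'   [compare_strategies()] result (or a single number, used directly as the
#'   statistic) for the model with parameter `name` set to `value`.
#' @param params data frame with columns `name`, `low`, `high` (and
#'   optionally `base`).
#' @param statistic `"auto"` uses the ICER when the base case and every
#'   endpoint have one, and the incremental net monetary benefit otherwise
#'   (dominance makes the ICER undefined or sign-ambiguous); or force
#'   `"icer"` / `"inmb"`.
#' @param wtp willingness-to-pay threshold for the iNMB statistic (USD per
#'   QALY).
#' @param base the base-case evaluation (defaults to
#'   `eval_fn(NULL, NULL)`).
#' @return data frame of class `tornado_result`: one row per parameter with
#'   low/high parameter values, low/high statistic values, and `width`;
#'   attribute `statistic` records which summary was used and
#'   attribute `base_value` its base-case value.
#' @export
tornado_analysis <- function(eval_fn, params,
                             statistic = c("auto", "icer", "inmb"),
                             wtp = 30000,
                             base = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("name", "low", "high") %in% names(params)))
  if (is.null(base)) base <- eval_fn(NULL, NULL)

  # evaluate every endpoint first so "auto" can see whether all runs carry
  # a defined ICER
  evals <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    lapply(c(low = p$low, high = p$high), function(v) {
      tryCatch(list(res = eval_fn(p$name, v), error = NA_character_),
               error = function(e) list(res = NULL,
                                        error = conditionMessage(e)))
    })
  })
  has_icer <- function(res) {
    is.numeric(res) || (!is.null(res) && !is.na(res$icer))
  }
  if (statistic == "auto") {
    all_res <- c(list(base), unlist(lapply(evals, function(e)
      list(e$low$res, e$high$res)), recursive = FALSE))
    defined <- vapply(all_res[!vapply(all_res, is.null, logical(1))],
                      has_icer, logical(1))
    statistic <- if (all(defined)) "icer" else "inmb"
  }
  summarize <- function(res) {
    if (is.null(res)) return(NA_real_)
    if (is.numeric(res)) return(unname(res))
    if (statistic == "icer") res$icer else inmb(res, wtp)
  }
  base_value <- summarize(base)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    ends <- evals[[i]]
    data.frame(
      name = p$name, low = p$low, high = p$high,
      value_low = summarize(ends$low$res),
      value_high = summarize(ends$high$res),
      width = abs(summarize(ends$high$res) - summarize(ends$low$res)),
      error = if (!is.na(ends$low$error)) ends$low$error else ends$high$error,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$width), -Inf, out$width)), ]
  rownames(out) <- NULL
  attr(out, "statistic") <- statistic
  attr(out, "base_value") <- base_value
  attr(out, "wtp") <- if (statistic == "inmb") wtp else NA_real_
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @export
print.tornado_result <- function(x, ...) {
  cat(sprintf("<tornado_result> statistic: %s (base %.4g)\n",
              attr(x, "statistic"), attr(x, "base_value")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
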