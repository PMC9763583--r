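#' Propensity-score 1:1 case/control matching
#'
#' Fits a logistic model of case status on age and sex, then greedily pairs
#' each case with the nearest unused control on the logit scale, within a
#' caliper of `caliper_sd` standard deviations of the logit. Cases are
#' matched hardest-first (descending propensity), the standard mitigation
#' of greedy-order bias; cases with no control inside the caliper are
#' reported unmatched rather than force-paired.
#'
#' @param meta a [sample_metadata] with `age` and `sex` present.
#' @param caliper_sd caliper width in SDs of the logit propensity.
#' @param seed integer seed (breaks exact distance ties reproducibly).
#' @return List of class `matched_cohort`: `pairs` (data.frame
#'   case_id/control_id), `unmatched_cases`, `coefficients`, `caliper`,
#'   `balance` (standardised mean difference of age before/after).
#' @export
propensity_match <- function(meta, caliper_sd = 0.2, seed = 1) {
  stopifnot(inherits(meta, "sample_metadata"))
  if (!all(c("age", "sex") %in% names(meta)))
    stop("metadata must contain age and sex")
  ok <- complete.cases(meta[, c("age", "sex", "group")])
  meta <- meta[ok, , drop = FALSE]
  y <- as_binary_labels(meta$group)
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("need at least one case and one control")
  sex_num <- as.numeric(as.factor(as.character(meta$sex)))
  fit <- glm(y ~ age + sex_num, data = data.frame(y = y, age = meta$age,
                                                  sex_num = sex_num),
             family = binomial())
  logit <- as.numeric(predict(fit))
  caliper <- caliper_sd * sd(logit)

  case_idx <- which(y == 1)
  ctrl_idx <- which(y == 0)
  case_idx <- case_idx[order(logit[case_idx], decreasing = TRUE)]
  set.seed(derive_seed(seed, "match"))
  used <- logical(length(logit))
  pairs <- list()
  unmatched <- character(0)
  for (ci in case_idx) {
    avail <- ctrl_idx[!used[ctrl_idx]]
    if (!length(avail)) { unmatched <- c(unmatched, meta$sample_id[ci]); next }
    dd <- abs(logit[avail] - logit[ci])
    ok2 <- dd <= caliper + 1e-12
    if (!any(ok2)) { unmatched <- c(unmatched, meta$sample_id[ci]); next }
    cand <- avail[ok2][dd[ok2] == min(dd[ok2])]
    pick <- if (length(cand) > 1) sample(cand, 1) else cand
    used[pick] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      case_id = meta$sample_id[ci], control_id = meta$sample_id[pick],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0))
  if (!nrow(pairs))
    warning("no case could be matched within the caliper")

  smd <- function(ids_case, ids_ctrl) {
    a <- meta$age[match(ids_case, meta$sample_id)]
    b <- meta$age[match(ids_ctrl, meta$sample_id)]
    s <- sqrt((var(a) + var(b)) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mean(a) - mean(b)) / s
  }
  balance <- c(
    before = smd(meta$sample_id[y == 1], meta$sample_id[y == 0]),
    after = if (nrow(pairs) >= 2) smd(pairs$case_id, pairs$control_id) else NA_real_)

  structure(list(pairs = pairs, unmatched_cases = unmatched,
                 coefficients = coef(fit), caliper = caliper,
                 caliper_sd = caliper_sd, balance = balance),
            class = "matched_cohort")
}

#' Split matched pairs into discovery and validation cohorts
#'
#' Pairs -- never individuals -- are randomised to the two sides so the 1:1
#' case/control structure survives the split. For pair counts not divisible
#' by the ratio, discovery receives the ceiling share (training data is
#' favoured, deterministically).
#'
#' @param m a `matched_cohort` from [propensity_match].
#' @param ratio integer pair `c(discovery, validation)` shares, default 2:1.
#' @param seed integer seed; identical seeds give identical splits.
#' @return List of class `cohort_split`: `discovery_ids`, `validation_ids`,
#'   `discovery_pairs`, `validation_pairs`, `seed`.
#' @export
split_discovery_validation <- function(m, ratio = c(2, 1), seed = 1) {
  stopifnot(inherits(m, "matched_cohort"))
  if (length(ratio) != 2 || any(ratio <= 0)) stop("ratio must be two positives")
  n <- nrow(m$pairs)
  if (n < 3) stop("need at least 3 matched pairs")
  n_disc <- ceiling(n * ratio[1] / sum(ratio))
  set.seed(derive_seed(seed, "split"))
  disc <- sort(sample(n, n_disc))
  dp <- m$pairs[disc, , drop = FALSE]
  vp <- m$pairs[-disc, , drop = FALSE]
  structure(list(
    discovery_ids = c(dp$case_id, dp$control_id),
    validation_ids = c(vp$case_id, vp$control_id),
    discovery_pairs = dp, validation_pairs = vp, seed = seed),
    class = "cohort_split")
}
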