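#' Fit a propensity-score model between two categories
#'
#' Logistic regression of membership in the treatment category on the
#' matching covariates (default age, height, smoking, COPD; sex is
#' excluded because severity cohorts of this kind are almost entirely
#' male and matching empties the female cells).
#'
#' @param cohort a `cohort_table` (or any data.frame with a `category`
#'   column and the covariates).
#' @param treatment_category,control_category category codes.
#' @param covariates covariate column names (must be complete).
#' @return An object of class `propensity_model`: list with `fit` (the
#'   glm), `data` (the two-category subset with a `score` column),
#'   `treatment_category`, `control_category`.
#' @export
fit_propensity <- function(cohort, treatment_category, control_category,
                           covariates = c("age", "height", "smoking",
                                          "copd")) {
  d <- cohort[cohort$category %in% c(treatment_category, control_category), ,
              drop = FALSE]
  if (!sum(d$category == treatment_category) ||
      !sum(d$category == control_category))
    stop("both categories must be nonempty")
  if (anyNA(d[covariates]))
    stop("matching covariates must be complete")
  d <- as.data.frame(d)
  d$.treat <- as.integer(d$category == treatment_category)
  f <- stats::as.formula(paste(".treat ~",
                               paste(covariates, collapse = " + ")))
  fit <- stats::glm(f, family = stats::binomial(), data = d)
  sc <- stats::fitted(fit)
  if (any(sc > 1 - 1e-10) || any(sc < 1e-10))
    stop("propensity model is (quasi-)separated: scores reach 0/1; ",
         "consider caliper-free exact matching on the covariates instead")
  d$score <- sc
  structure(list(fit = fit, data = d,
                 treatment_category = treatment_category,
                 control_category = control_category),
            class = "propensity_model")
}

#' Greedy one-to-one nearest-score matching
#'
#' Treatment subjects are processed in descending propensity-score order
#' (ties broken by ascending subject id); each takes the unused control
#' with the smallest absolute score difference.  With `use_caliper`,
#' pairs whose score difference exceeds the caliper are refused and the
#' treatment subject is dropped.  Unmatched treatment subjects (e.g. when
#' controls run out) are recorded, not an error.
#'
#' @param model a [fit_propensity()] result.
#' @param use_caliper logical.
#' @param caliper caliper width in score units; default 0.4 times the
#'   standard deviation of the pooled scores (set `caliper_on_logit =
#'   TRUE` to use 0.4 SD of the logit of the score instead).
#' @param caliper_on_logit compute distance and caliper on the logit
#'   scale.
#' @return An object of class `matched_cohort`: list with `pairs`
#'   (data.frame `treat_id`, `control_id`, `delta`), `dropped` (treatment
#'   ids), `caliper`.
#' @export
greedy_match <- function(model, use_caliper = TRUE, caliper = NULL,
                         caliper_on_logit = FALSE) {
  stopifnot(inherits(model, "propensity_model"))
  d <- model$data
  sc <- if (caliper_on_logit) stats::qlogis(d$score) else d$score
  if (is.null(caliper)) caliper <- 0.4 * stats::sd(sc)
  if (!use_caliper) caliper <- Inf
  ti <- which(d$.treat == 1L)
  ci <- which(d$.treat == 0L)
  ord <- ti[order(-sc[ti], d$id[ti])]
  used <- rep(FALSE, length(ci))
  pairs <- list()
  dropped <- integer(0)
  for (i in ord) {
    delta <- abs(sc[ci] - sc[i])
    delta[used] <- Inf
    j <- which.min(delta)
    if (is.finite(delta[j]) && delta[j] <= caliper) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(treat_id = d$id[i], control_id = d$id[ci[j]],
                   delta = delta[j])
    } else {
      dropped <- c(dropped, d$id[i])
    }
  }
  structure(list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treat_id = integer(0), control_id = integer(0),
               delta = numeric(0)),
    dropped = dropped, caliper = caliper),
    class = "matched_cohort")
}

#' Two-stage propensity matching across severity categories
#'
#' Stage 1: the smallest matched category (default 2) is the treatment
#' group and the largest (default 0) the control group; greedy one-to-one
#' matching within a caliper of 0.4 SD of the pooled scores.  Stage 2:
#' the stage-1-retained control-category subjects become the treatment
#' group and are matched caliper-free, one-to-one, against each remaining
#' category (defaults 1 and 4; category 3 is excluded for its small
#' sample).  The result is one equal-sized group per matched category.
#'
#' @param cohort a `cohort_table`.
#' @param stage1 length-2: treatment and control category of stage 1.
#' @param stage2_controls categories matched caliper-free against the
#'   retained stage-1 control set.
#' @param caliper_factor caliper in pooled-score SD units (default 0.4).
#' @param covariates matching covariates.
#' @return List of class `two_stage_match`: `groups` (named list of
#'   retained subject ids per category), `n_per_group`, `audit` (per-stage
#'   pair tables, calipers and drops), `cohort` (the retained rows).
#' @export
two_stage_match <- function(cohort, stage1 = c(2, 0),
                            stage2_controls = c(1, 4),
                            caliper_factor = 0.4,
                            covariates = c("age", "height", "smoking",
                                           "copd")) {
  for (cc in c(stage1, stage2_controls))
    if (!sum(cohort$category == cc))
      stop("category ", cc, " is empty")
  m1 <- fit_propensity(cohort, stage1[1], stage1[2], covariates)
  cal <- caliper_factor * stats::sd(m1$data$score)
  g1 <- greedy_match(m1, use_caliper = TRUE, caliper = cal)
  if (!nrow(g1$pairs)) stop("stage 1 matching emptied the treatment group")
  groups <- list()
  groups[[as.character(stage1[1])]] <- sort(g1$pairs$treat_id)
  groups[[as.character(stage1[2])]] <- sort(g1$pairs$control_id)
  audit <- list(stage1 = list(pairs = g1$pairs, caliper = cal,
                              dropped = g1$dropped))
  retained0 <- cohort[cohort$id %in% g1$pairs$control_id, , drop = FALSE]
  for (cc in stage2_controls) {
    pool <- rbind(retained0, cohort[cohort$category == cc, , drop = FALSE])
    m2 <- fit_propensity(pool, stage1[2], cc, covariates)
    g2 <- greedy_match(m2, use_caliper = FALSE)
    if (!nrow(g2$pairs))
      stop("stage 2 matching emptied category ", cc)
    groups[[as.character(cc)]] <- sort(g2$pairs$control_id)
    audit[[paste0("stage2_cat", cc)]] <-
      list(pairs = g2$pairs, caliper = Inf, dropped = g2$dropped)
  }
  sizes <- vapply(groups, length, integer(1))
  if (length(unique(sizes)) != 1L)
    warning("matched groups are not equal-sized (controls exhausted): ",
            paste(sizes, collapse = ", "))
  keep <- cohort[cohort$id %in% unlist(groups) &
                   cohort$category %in% as.numeric(names(groups)), ,
                 drop = FALSE]
  structure(list(groups = groups, n_per_group = sizes, audit = audit,
                 cohort = keep),
            class = "two_stage_match")
}

#' @export
print.two_stage_match <- function(x, ...) {
  cat("<two_stage_match> groups:",
      paste(names(x$n_per_group), "=", x$n_per_group, collapse = ", "),
      "\n")
  invisible(x)
}

# pairwise SMD, continuous: |m1-m2| / sqrt((s1^2+s2^2)/2)
smd_pair_continuous <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("continuous SMD needs at least 2 observations per group")
  num <- abs(mean(x1) - mean(x2))
  den <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  if (num == 0 && den == 0) return(0)
  num / den
}

# pairwise SMD, binary: |p1-p2| / sqrt((p1(1-p1)+p2(1-p2))/2); 0/0 -> 0
smd_pair_binary <- function(x1, x2) {
  p1 <- mean(x1); p2 <- mean(x2)
  num <- abs(p1 - p2)
  den2 <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (num == 0 && den2 == 0) return(0)
  num / sqrt(den2)
}

#' Standardized mean differences across groups
#'
#' For each variable, all pairwise standardized mean differences between
#' groups and a multi-group summary.  Continuous variables use the
#' pooled-variance denominator `sqrt((s1^2+s2^2)/2)`; binary (0/1)
#' variables use `sqrt((p1(1-p1)+p2(1-p2))/2)`; a pair with zero
#' difference and zero variance is defined as SMD 0.  The multi-group
#' summary is the arithmetic mean of all pairwise SMDs (`summary =
#' "max"` gives the maximum instead); a variable is flagged balanced when
#' the summary is below 0.1, the conventional balance threshold.
#'
#' @param data data.frame of subjects.
#' @param group grouping column name (default `"category"`).
#' @param vars variable names; binary variables are detected
#'   automatically (all values in 0/1).
#' @param summary `"mean"` (average of pairwise SMDs) or `"max"`.
#' @return An object of class `smd_table`: data.frame with `variable`,
#'   `smd`, `balanced`; pairwise matrices in `attr(, "pairwise")`.
#' @export
smd <- function(data, vars, group = "category", summary = c("mean", "max")) {
  summary <- match.arg(summary)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  pairw <- list()
  out <- lapply(vars, function(v) {
    xs <- split(data[[v]], g)
    binary <- all(unlist(xs) %in% c(0, 1, NA))
    cb <- utils::combn(nlevels(g), 2)
    m <- matrix(NA_real_, nlevels(g), nlevels(g),
                dimnames = list(levels(g), levels(g)))
    vals <- apply(cb, 2, function(pr) {
      x1 <- xs[[pr[1]]]; x2 <- xs[[pr[2]]]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      s <- if (binary) smd_pair_binary(x1, x2)
      else smd_pair_continuous(x1, x2)
      m[pr[1], pr[2]] <<- m[pr[2], pr[1]] <<- s
      s
    })
    pairw[[v]] <<- m
    data.frame(variable = v,
               smd = if (summary == "mean") mean(vals) else max(vals))
  })
  res <- do.call(rbind, out)
  res$balanced <- res$smd < 0.1
  class(res) <- c("smd_table", "data.frame")
  attr(res, "pairwise") <- pairw
  res
}

#' Binary multi-group SMD from group counts
#'
#' Convenience for balance columns printed as percentages: given event
#' counts and group sizes, reconstructs the 0/1 data and returns the mean
#' of all pairwise binary SMDs (pairs with zero difference and zero
#' variance count as 0).
#'
#' @param events number of events per group.
#' @param sizes group sizes.
#' @return The multi-group SMD (mean of pairwise SMDs).
#' @export
smd_binary_counts <- function(events, sizes) {
  stopifnot(length(events) == length(sizes), all(events <= sizes))
  d <- data.frame(
    g = rep(seq_along(sizes), sizes),
    x = unlist(lapply(seq_along(sizes), function(i)
      rep(c(1, 0), c(events[i], sizes[i] - events[i])))))
  smd(d, vars = "x", group = "g")$smd
}
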