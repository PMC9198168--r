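# Multinomial-logit odds-ratio analyses: L1-penalized variable selection
# followed by an unpenalized refit. Two feature builders share one fitter:
# next-year spend-group membership, and the count of top-decile years over a
# three-year horizon.

# default predictor universe built from a year of member rows
build_feature_frame <- function(rows) {
  dt <- data.table(member_id = rows$member_id)
  for (cc in CHRONIC_CONDITION_NAMES) {
    dt[, (cc) := has_any_token(rows$chronic_conditions, cc)]
  }
  for (fc in frailty_component_names()) {
    dt[, (paste0("frail_", fc)) := has_any_token(rows$frailty_components, fc)]
  }
  for (dc in persistent_drug_classes()) {
    dt[, (paste0("drug_", dc)) := has_any_token(rows$drug_categories, dc)]
  }
  for (pc in c("dme_supplies", "chest_xray", "nonhospital_care")) {
    dt[, (paste0("proc_", pc)) := has_any_token(rows$procedure_categories, pc)]
  }
  dt[, `:=`(
    esrd_or_dialysis = rows$esrd_or_dialysis,
    dual_eligible = rows$dual_eligible,
    female = rows$sex == "F",
    age = as.numeric(rows$age),
    ses_index = rows$ses_index,
    n_drug_categories = as.numeric(count_tokens(rows$drug_categories)),
    n_procedure_categories =
      as.numeric(count_tokens(rows$procedure_categories)),
    hospital_days = as.numeric(rows$hospital_days),
    distinct_providers = as.numeric(rows$distinct_providers),
    distinct_specialties = as.numeric(rows$distinct_specialties)
  )]
  setattr(dt, "continuous",
          c("age", "ses_index", "n_drug_categories",
            "n_procedure_categories", "hospital_days",
            "distinct_providers", "distinct_specialties"))
  dt
}

#' Feature matrix for the next-year spend-group model
#'
#' One row per member classified in year `year_t + 1`, with predictors taken
#' strictly from the member's year-t row and outcome equal to the year-t+1
#' spend group (`BOTTOM90` is the natural reference class).
#'
#' @param panel A member-year panel.
#' @param groups [classify_groups()] output covering year `year_t + 1`.
#' @param year_t Predictor year.
#' @return `data.table` with `member_id`, an `outcome` factor and the
#'   predictor columns; the names of continuous predictors are recorded in
#'   `attr(, "continuous")`.
#' @export
build_spend_group_features <- function(panel, groups, year_t) {
  panel <- as.data.table(panel)
  groups <- as.data.table(groups)
  yt <- as.integer(year_t)
  g1 <- groups[groups$year == yt + 1L]
  if (!nrow(g1)) {
    stop("outcome year ", yt + 1L, " has not been classified", call. = FALSE)
  }
  rows <- panel[panel$year == yt]
  keep <- g1[g1$member_id %in% rows$member_id]
  ff <- build_feature_frame(rows[match(keep$member_id, rows$member_id)])
  cont <- attr(ff, "continuous")
  ff[, outcome := factor(keep$group, levels = GROUP_LEVELS)]
  setcolorder(ff, c("member_id", "outcome"))
  setattr(ff, "continuous", cont)
  setattr(ff, "reference", "BOTTOM90")
  ff[]
}

#' Feature matrix for the top-decile persistence model
#'
#' One row per member with a baseline-year row; the outcome is the number of
#' years the member spends in the top decile over the three years following
#' `baseline_year` (0-3, reference 0), and predictors come from the baseline
#' year only.
#'
#' @param panel A member-year panel spanning at least four years.
#' @param assignments Decile assignments covering the three outcome years.
#' @param baseline_year Predictor year (first panel year).
#' @return As [build_spend_group_features()], with outcome levels
#'   `"0".."3"`.
#' @export
build_persistence_features <- function(panel, assignments, baseline_year) {
  panel <- as.data.table(panel)
  assignments <- as.data.table(assignments)
  by_ <- as.integer(baseline_year)
  horizon <- (by_ + 1L):(by_ + 3L)
  if (!all(horizon %in% unique(assignments$year))) {
    stop("persistence outcome needs decile assignments for ",
         paste(horizon, collapse = ", "), " (four panel years)",
         call. = FALSE)
  }
  rows <- panel[panel$year == by_]
  top <- assignments[assignments$year %in% horizon & assignments$decile == 10L]
  n_top <- top[, .N, by = member_id]
  outcome_n <- n_top$N[match(rows$member_id, n_top$member_id)]
  outcome_n[is.na(outcome_n)] <- 0L
  ff <- build_feature_frame(rows)
  cont <- attr(ff, "continuous")
  ff[, outcome := factor(outcome_n, levels = 0:3)]
  setcolorder(ff, c("member_id", "outcome"))
  setattr(ff, "continuous", cont)
  setattr(ff, "reference", "0")
  ff[]
}

#' L1-penalized multinomial logit with unpenalized refit
#'
#' Two-step odds-ratio estimation. Step 1 fits an L1-penalized multinomial
#' logistic regression over the predictors (continuous predictors
#' standardized, binary ones left as 0/1), choosing the penalty on a
#' geometric grid by cross-validated deviance with seeded fold assignment;
#' predictors with any nonzero coefficient at the selected penalty are
#' retained -- the penalty's role is to discard redundant, collinear
#' predictors. Step 2 refits an unpenalized multinomial logit on the
#' retained predictors at their original scale and reports exponentiated
#' coefficients with Wald standard errors and p-values against the reference
#' class.
#'
#' Exactly duplicated predictor columns are reduced to their first copy
#' before selection, so at most one of a perfectly collinear pair can be
#' retained.
#'
#' @param features A feature table from [build_spend_group_features()] or
#'   [build_persistence_features()] (columns `member_id`, `outcome`,
#'   predictors).
#' @param penalty_grid Optional decreasing vector of penalty values; by
#'   default a geometric grid of 20 points chosen from the data.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param reference Reference outcome class (default: the level recorded by
#'   the feature builder, else the first factor level).
#' @return A list of class `mlogit_or_fit` with `table` (`data.table`:
#'   `feature`, `class_label`, `or`, `se` (log-OR scale), `p_value`),
#'   `selected`, `reference`, `lambda`, and the refit object as `fit`.
#' @export
fit_mlogit_l1 <- function(features, penalty_grid = NULL, cv_folds = 5L,
                          seed = 1L, reference = NULL) {
  features <- as.data.table(features)
  y <- features$outcome
  if (is.null(y)) stop("features must contain an 'outcome' column",
                       call. = FALSE)
  y <- droplevels(factor(y))
  tab <- table(y)
  if (length(tab) < 2L || any(tab < 50L)) {
    stop("each outcome class needs at least 50 rows (got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")",
         call. = FALSE)
  }
  reference <- reference %||% attr(features, "reference") %||% levels(y)[1L]
  y <- stats::relevel(y, ref = reference)

  pred_cols <- setdiff(names(features), c("member_id", "outcome"))
  X <- as.matrix(features[, lapply(.SD, as.numeric), .SDcols = pred_cols])
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  X <- X[, keep, drop = FALSE]
  # drop exact duplicate columns (perfect collinearity)
  dup <- duplicated(t(X))
  if (any(dup)) X <- X[, !dup, drop = FALSE]
  pred_cols <- colnames(X)

  cont <- intersect(attr(features, "continuous") %||% character(0), pred_cols)
  Xs <- X
  for (cc in cont) Xs[, cc] <- as.numeric(scale(Xs[, cc]))

  set.seed(as.integer(seed))
  lambda_min <- NA_real_
  if (length(pred_cols) < 2L) {
    selected <- pred_cols  # nothing to select among
  } else {
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(Xs)))
    cv_args <- list(x = Xs, y = y, family = "multinomial",
                    type.measure = "deviance", foldid = foldid,
                    standardize = FALSE)
    if (is.null(penalty_grid)) cv_args$nlambda <- 20L else {
      cv_args$lambda <- penalty_grid
    }
    cv <- do.call(glmnet::cv.glmnet, cv_args)
    lambda_min <- cv$lambda.min
    co <- coef(cv, s = "lambda.min")
    nz <- Reduce(`|`, lapply(co, function(m) {
      as.matrix(m)[-1L, 1L] != 0
    }))
    selected <- pred_cols[nz[pred_cols]]
  }
  if (!length(selected)) {
    stop("the L1 step selected no features; supply a weaker penalty grid",
         call. = FALSE)
  }

  refit_df <- data.frame(.outcome = y, X[, selected, drop = FALSE],
                         check.names = FALSE)
  fit <- nnet::multinom(.outcome ~ ., data = refit_df, trace = FALSE,
                        maxit = 500L, Hess = TRUE)
  # rare feature-by-class cells can make the Hessian near-singular; their
  # standard errors surface as NaN rather than being dropped
  sm <- suppressWarnings(summary(fit))
  B <- sm$coefficients
  SE <- sm$standard.errors
  if (is.null(dim(B))) {  # two-class fit returns vectors
    B <- matrix(B, nrow = 1L, dimnames = list(setdiff(levels(y), reference),
                                              names(sm$coefficients)))
    SE <- matrix(SE, nrow = 1L, dimnames = dimnames(B))
  }
  # separation check on the scale of one within-sample SD per predictor
  sds <- apply(X[, selected, drop = FALSE], 2L, sd)
  Bstd <- sweep(B[, selected, drop = FALSE], 2L, sds, `*`)
  if (any(abs(Bstd) > 15)) {
    worst <- selected[which.max(apply(abs(Bstd), 2L, max))]
    stop("separation detected: unbounded coefficient for feature '", worst,
         "'", call. = FALSE)
  }

  classes <- rownames(B)
  or_tab <- rbindlist(lapply(classes, function(cl) {
    b <- B[cl, selected]
    s <- SE[cl, selected]
    data.table(feature = selected, class_label = cl, or = exp(b), se = s,
               p_value = 2 * pnorm(-abs(b / s)))
  }))
  structure(list(table = or_tab, selected = selected, reference = reference,
                 lambda = lambda_min, fit = fit),
            class = "mlogit_or_fit")
}
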