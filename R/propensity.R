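#' Fit a large-scale L1-regularised propensity model
#'
#' Penalised logistic regression of target-arm membership on all baseline
#' covariates, maximising the penalised log-likelihood
#' \eqn{\ell(\beta) - \lambda \sum_j |\beta_j|} with an unpenalised
#' intercept. The penalty weight is selected by k-fold cross-validated
#' held-out likelihood over a log-spaced grid. Covariates enter
#' unstandardised, with the penalty on the raw coefficient scale. Fitted
#' via coordinate descent (glmnet).
#'
#' @param covariates a \code{covariate_matrix} from [extract_covariates()]
#'   (or any matrix with column names).
#' @param arm character/factor vector, one entry per covariate row, with
#'   values \code{"target"} and \code{"comparator"}.
#' @param lambda_grid numeric vector of penalty values on the glmnet
#'   (per-observation) scale; default 20 points log-spaced over
#'   \code{[1e-4, 1e2] / n}.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return an object of class \code{ps_model}: slope coefficients,
#'   intercept, the selected \code{lambda}, and the cross-validation table
#'   (\code{lambda}, mean held-out binomial deviance).
#' @export
fit_propensity_model <- function(covariates, arm, lambda_grid = NULL,
                                 folds = 10L, seed = 1L) {
  x <- if (inherits(covariates, "covariate_matrix")) covariates$matrix
       else covariates
  y <- as.integer(arm == "target")
  if (length(y) != nrow(x))
    stopf("arm labels and covariate rows differ in length",
          class = "vaxsafety_input_error")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stopf("need at least two persons in each arm to fit a propensity model",
          class = "vaxsafety_input_error")
  n <- nrow(x)
  if (is.null(lambda_grid))
    lambda_grid <- 10^seq(2, -4, length.out = 20L) / n
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  if (length(lambda_grid) == 1L) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = lambda_grid, standardize = FALSE)
    beta <- as.numeric(fit$beta)
    names(beta) <- rownames(fit$beta)
    model <- list(coefficients = beta,
                  intercept = as.numeric(fit$a0),
                  lambda = lambda_grid,
                  cv = NULL)
  } else {
    folds <- max(2L, min(as.integer(folds), n))
    foldid <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lambda_grid, standardize = FALSE,
                            foldid = foldid, type.measure = "deviance")
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    names(beta) <- colnames(x)
    model <- list(coefficients = beta,
                  intercept = as.numeric(stats::coef(cv,
                                                     s = "lambda.min"))[1],
                  lambda = cv$lambda.min,
                  cv = data.frame(lambda = cv$lambda,
                                  cv_deviance = cv$cvm))
  }
  model$n <- n
  class(model) <- "ps_model"
  model
}

#' @export
print.ps_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("L1-regularised propensity model: %d covariates (%d non-zero), lambda = %.3g\n",
              length(x$coefficients), nz, x$lambda))
  invisible(x)
}

#' @export
coef.ps_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Per-person logit propensity score
#'
#' \code{intercept + sum(beta * x)}, matching covariates by id; covariate
#' columns unseen at fit time contribute coefficient 0.
#'
#' @param model a [fit_propensity_model()] result.
#' @param covariates a \code{covariate_matrix} or column-named matrix.
#' @return numeric vector of logits.
#' @export
predict_logit <- function(model, covariates) {
  x <- if (inherits(covariates, "covariate_matrix")) covariates$matrix
       else covariates
  shared <- intersect(colnames(x), names(model$coefficients))
  lp <- rep(model$intercept, nrow(x))
  if (length(shared))
    lp <- lp + as.numeric(x[, shared, drop = FALSE] %*%
                            model$coefficients[shared])
  lp
}

#' Greedy variable-ratio caliper matching on the propensity logit
#'
#' The smaller cohort is the base side (reverse orientation when the
#' target cohort is larger). The caliper is \code{caliper_sd} times the
#' standard deviation of the logit pooled over both arms. Matching runs in
#' rounds 1..\code{max_ratio}: in each round the base subjects are visited
#' in a seeded random order and each is paired with its nearest unmatched
#' candidate inside the caliper (exact-distance ties go to the lowest
#' person id). Base subjects with no match after round 1 are dropped;
#' rounds 2 and up are best-effort, so matched sets hold 1 to
#' \code{max_ratio} candidates. When all logits are equal the caliper is 0
#' and exact-tie matching is still allowed.
#'
#' @param logit_target,logit_comparator per-person logits.
#' @param id_target,id_comparator person ids (default positional).
#' @param caliper_sd caliper width in pooled-SD units (default 0.2).
#' @param max_ratio maximum candidates per base subject (default 4).
#' @param seed integer seed for the visiting order.
#' @return an object of class \code{matched_sets}: a data.frame with
#'   columns \code{set_id}, \code{role} (\code{base}/\code{candidate}) and
#'   \code{person_id}; attributes \code{orientation} (\code{normal} when
#'   the target side is the base, else \code{reverse}) and \code{caliper}.
#' @export
greedy_match <- function(logit_target, logit_comparator,
                         id_target = seq_along(logit_target),
                         id_comparator = seq_along(logit_comparator),
                         caliper_sd = 0.2, max_ratio = 4L, seed = 1L) {
  if (!length(logit_target) || !length(logit_comparator))
    stopf("both arms must be non-empty", class = "vaxsafety_input_error")
  pooled_sd <- stats::sd(c(logit_target, logit_comparator))
  caliper <- if (!is.finite(pooled_sd)) 0 else caliper_sd * pooled_sd

  reverse <- length(logit_target) > length(logit_comparator)
  if (reverse) {
    base_logit <- logit_comparator; base_id <- id_comparator
    cand_logit <- logit_target; cand_id <- id_target
  } else {
    base_logit <- logit_target; base_id <- id_target
    cand_logit <- logit_comparator; cand_id <- id_comparator
  }
  ord <- order(cand_logit, cand_id)
  cand_logit_s <- as.numeric(cand_logit[ord])
  cand_id_s <- as.integer(cand_id[ord])
  nb <- length(base_logit)
  round_orders <- with_seed(seed, {
    vapply(seq_len(max_ratio), function(r) sample.int(nb), integer(nb))
  })
  if (nb == 1L) round_orders <- matrix(round_orders, nrow = 1L)

  mm <- greedy_match_core(as.numeric(base_logit), cand_logit_s, cand_id_s,
                          caliper, as.integer(max_ratio), round_orders)
  matched <- which(mm[, 1] != 0L)
  if (length(matched)) {
    sub <- mm[matched, , drop = FALSE]
    k <- rowSums(sub != 0L)
    cand_vec <- as.integer(t(sub))
    cand_vec <- cand_vec[cand_vec != 0L]
    out <- data.frame(
      set_id = c(seq_along(matched), rep(seq_along(matched), k)),
      role = c(rep("base", length(matched)),
               rep("candidate", length(cand_vec))),
      person_id = c(as.integer(base_id[matched]), cand_vec),
      stringsAsFactors = FALSE)
    out <- out[order(out$set_id, out$role), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(set_id = integer(0), role = character(0),
                      person_id = integer(0), stringsAsFactors = FALSE)
  }
  attr(out, "orientation") <- if (reverse) "reverse" else "normal"
  attr(out, "caliper") <- caliper
  class(out) <- c("matched_sets", "data.frame")
  out
}

#' Person ids per arm of a matching result
#'
#' @param matches a [greedy_match()] result.
#' @return \code{list(target = ids, comparator = ids)}.
#' @export
matched_persons <- function(matches) {
  base <- matches$person_id[matches$role == "base"]
  cand <- matches$person_id[matches$role == "candidate"]
  if (identical(attr(matches, "orientation"), "reverse"))
    list(target = cand, comparator = base)
  else
    list(target = base, comparator = cand)
}

#' Standardised mean differences between matched arms
#'
#' \eqn{SMD = (\bar x_t - \bar x_c) / \sqrt{(s_t^2 + s_c^2)/2}} with
#' \eqn{s^2 = p(1-p)} for binary covariates. When both variances are 0 the
#' SMD is 0 if the means agree and flagged undefined otherwise.
#'
#' @param covariates a \code{covariate_matrix} (rows indexed by
#'   \code{person_id}).
#' @param persons_target,persons_comparator person ids per arm (at least 2
#'   each).
#' @return data.frame: \code{covariate_id}, \code{mean_target},
#'   \code{mean_comparator}, \code{smd}, \code{undefined}.
#' @export
compute_smd <- function(covariates, persons_target, persons_comparator) {
  if (length(persons_target) < 2L || length(persons_comparator) < 2L)
    stopf("need at least two persons per arm to compute SMDs",
          class = "vaxsafety_input_error")
  it <- match(persons_target, covariates$person_id)
  ic <- match(persons_comparator, covariates$person_id)
  if (anyNA(it) || anyNA(ic))
    stopf("matched person missing from covariate matrix",
          class = "vaxsafety_input_error")
  xt <- covariates$matrix[it, , drop = FALSE]
  xc <- covariates$matrix[ic, , drop = FALSE]
  binary <- covariates$meta$type %in% c("binary", "one_hot")

  col_stats <- function(m) {
    mu <- Matrix::colMeans(m)
    ex2 <- Matrix::colMeans(m^2)
    n <- nrow(m)
    v <- pmax(0, (ex2 - mu^2) * n / (n - 1))
    list(mean = mu, var = v)
  }
  st <- col_stats(xt); sc <- col_stats(xc)
  vt <- ifelse(binary, st$mean * (1 - st$mean), st$var)
  vc <- ifelse(binary, sc$mean * (1 - sc$mean), sc$var)
  pooled <- sqrt((vt + vc) / 2)
  diff <- st$mean - sc$mean
  smd <- diff / pooled
  zero_var <- pooled == 0
  undefined <- zero_var & abs(diff) > 1e-12
  smd[zero_var & !undefined] <- 0
  smd[undefined] <- NA_real_
  data.frame(covariate_id = colnames(covariates$matrix),
             mean_target = as.numeric(st$mean),
             mean_comparator = as.numeric(sc$mean),
             smd = as.numeric(smd),
             undefined = undefined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pre/post-matching balance table
#'
#' @param smd_pre,smd_post [compute_smd()] results before and after
#'   matching.
#' @return data.frame \code{covariate_id}, \code{smd_pre},
#'   \code{smd_post}, \code{undefined}; attribute \code{max_abs_post}.
#' @export
balance_table <- function(smd_pre, smd_post) {
  out <- merge(smd_pre[, c("covariate_id", "smd")],
               smd_post[, c("covariate_id", "smd", "undefined")],
               by = "covariate_id", suffixes = c("_pre", "_post"))
  names(out) <- c("covariate_id", "smd_pre", "smd_post", "undefined")
  attr(out, "max_abs_post") <- suppressWarnings(
    max(abs(out$smd_post), na.rm = TRUE))
  out
}

#' Measured-confounding balance gate
#'
#' Passes iff every post-match covariate SMD has absolute value strictly
#' below the threshold (covariates with an undefined SMD fail).
#'
#' @param balance a [balance_table()] (or any data.frame with
#'   \code{covariate_id} and \code{smd_post} or \code{smd} columns).
#' @param threshold strict SMD bound (default 0.1).
#' @return \code{list(pass = logical, max_abs_smd = numeric, offending =
#'   character vector of covariate ids)}.
#' @export
balance_gate <- function(balance, threshold = 0.1) {
  smd <- balance$smd_post %||% balance$smd
  undef <- balance$undefined %||% rep(FALSE, length(smd))
  bad <- undef | is.na(smd) | abs(smd) >= threshold
  list(pass = !any(bad),
       max_abs_smd = suppressWarnings(max(abs(smd), na.rm = TRUE)),
       offending = balance$covariate_id[bad])
}
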