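# Regulon-composite prognostic risk model: univariate Cox screening
# followed by L1-penalized (LASSO) Cox regression with cross-validated
# penalty, and the resulting linear risk score RS = sum(coef_i * score_i).

#' Fit the regulon risk model
#'
#' Stage 1 screens every candidate regulon by univariate Cox regression and
#' keeps those with Wald `p < p_uni`. Stage 2 fits an L1-penalized Cox model
#' over the survivors with the penalty chosen at the 10-fold
#' cross-validated partial-deviance minimum; the nonzero coefficients at
#' that penalty define the model. With a single stage-1 survivor the
#' coefficient is the unpenalized Cox estimate. An empty stage-1 set
#' returns an empty model with an explicit status rather than an error.
#'
#' @param scores Tibble with `patient` plus one column per candidate
#'   regulon.
#' @param records Survival tibble covering the same patients.
#' @param p_uni Univariate retention threshold (default 0.05).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @param min_events Minimum number of events (default 30).
#' @return Object of class `risk_model`: list with `regulons`,
#'   `coefficients` (named, nonzero), `lambda`, `univariate` (tibble),
#'   `status` (`"ok"`, `"single"` or `"empty"`), `folds`, `seed`.
#' @export
fit_risk_model <- function(scores, records, p_uni = 0.05, folds = 10,
                           seed = 1L, min_events = 30) {
  records <- validate_survival(records)
  stopifnot("patient" %in% names(scores))
  idx <- match(records$patient, scores$patient)
  if (anyNA(idx)) stop("scores missing patients", call. = FALSE)
  x <- as.matrix(scores[idx, setdiff(names(scores), "patient"), drop = FALSE])
  if (ncol(x) < 2) stop("need >= 2 candidate regulons", call. = FALSE)
  if (sum(records$event) < min_events) {
    stop("fewer than ", min_events, " events", call. = FALSE)
  }
  y <- survival::Surv(records$time, records$event)
  uni <- purrr::map_dfr(colnames(x), function(nm) {
    fit <- survival::coxph(y ~ x[, nm], ties = "efron")
    s <- summary(fit)
    tibble::tibble(regulon = nm,
                   beta = unname(s$coefficients[1, "coef"]),
                   hr = unname(s$coefficients[1, "exp(coef)"]),
                   p_value = unname(s$coefficients[1, "Pr(>|z|)"]))
  })
  survivors <- uni$regulon[uni$p_value < p_uni]
  base <- list(univariate = uni, folds = as.integer(folds),
               seed = as.integer(seed), p_uni = p_uni)
  if (length(survivors) == 0) {
    return(structure(c(list(regulons = character(),
                            coefficients = double(), lambda = NA_real_,
                            status = "empty"), base),
                     class = "risk_model"))
  }
  if (length(survivors) == 1) {
    fit <- survival::coxph(y ~ x[, survivors], ties = "efron")
    cf <- stats::setNames(unname(stats::coef(fit)), survivors)
    return(structure(c(list(regulons = survivors, coefficients = cf,
                            lambda = 0, status = "single"), base),
                     class = "risk_model"))
  }
  xs <- x[, survivors, drop = FALSE]
  fold_id <- withr::with_seed(derive_seed(seed, "lasso_folds"),
                              sample(rep_len(seq_len(folds), nrow(xs))))
  cv <- glmnet::cv.glmnet(xs, y, family = "cox", alpha = 1,
                          foldid = fold_id)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  nz <- cf[cf != 0]
  structure(c(list(regulons = names(nz), coefficients = nz,
                   lambda = cv$lambda.min, status = "ok"), base),
            class = "risk_model")
}

#' Print a `risk_model` summary
#' @param x Object to print.
#' @param ... Unused.
#' @method print risk_model
#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "risk_model (%s): %d/%d candidates pass univariate screen, %d selected\n",
    x$status, sum(x$univariate$p_value < x$p_uni), nrow(x$univariate),
    length(x$coefficients)))
  if (length(x$coefficients)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @describeIn fit_risk_model Coefficients as a tibble.
#' @param x A `risk_model`.
#' @param ... Unused.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(term = x$regulons,
                 estimate = unname(x$coefficients))
}

#' @describeIn fit_risk_model One-row model summary.
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$univariate),
    n_univariate = sum(x$univariate$p_value < x$p_uni),
    n_selected = length(x$coefficients),
    lambda = x$lambda,
    status = x$status
  )
}

#' Linear regulon risk score
#'
#' `RS = sum_i coef_i * score_i` over the model's regulons; a plain dot
#' product with no intercept.
#'
#' @param scores Tibble with `patient` plus regulon score columns covering
#'   the model's regulons.
#' @param model A `risk_model`.
#' @return Tibble `patient`, `rs`.
#' @export
risk_score <- function(scores, model) {
  stopifnot(inherits(model, "risk_model"), "patient" %in% names(scores))
  missing <- setdiff(model$regulons, names(scores))
  if (length(missing)) {
    stop("missing regulon columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rs <- if (length(model$regulons) == 0) {
    rep(0, nrow(scores))
  } else {
    as.numeric(as.matrix(scores[, model$regulons, drop = FALSE]) %*%
                 model$coefficients)
  }
  tibble::tibble(patient = scores$patient, rs = rs)
}
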