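# propensity-score estimation: exposure ~ baseline covariates, binomial logistic model

#' Default propensity-model covariate set
#'
#' Age, sex, the binarized cardiovascular risk-factor burden (2-4 vs 0-1
#' factors), coronary artery disease, valvular disease, heart failure, heart
#' failure medications (ACE inhibitor/ARB, beta-blocker), cytogenetic risk
#' group, AML history, and cumulative anthracycline dose. Fully overridable.
#'
#' @return Character vector of covariate names.
#' @export
default_ps_covariates <- function() {
  c("age", "sex", "cv_risk_high", "cad", "valvular_disease", "heart_failure",
    "acei_arb", "beta_blocker", "cytogenetic_risk", "aml_history",
    "anthracycline_dose")
}

#' Restrict a cohort to one model's comparison groups
#'
#' Model 1 compares IDH2-mutated (exposed) with IDH1/2-wildtype patients and
#' drops IDH1-mutated patients; model 2 compares the pooled IDH1/2-mutated
#' group (exposed) with wildtype.
#'
#' @param cohort cohort data frame.
#' @param model `"model1"` or `"model2"`.
#' @return List with elements `cohort` (the subset) and `exposed` (logical).
#' @export
model_subset <- function(cohort, model = c("model2", "model1")) {
  model <- match.arg(model)
  if (model == "model1") {
    keep <- cohort$exposure_group %in% c("WT", "IDH2")
    sub <- cohort[keep, , drop = FALSE]
    exposed <- sub$exposure_group == "IDH2"
  } else {
    sub <- cohort
    exposed <- sub$exposure_group %in% c("IDH1", "IDH2")
  }
  list(cohort = sub, exposed = exposed)
}

# expand one covariate name into reference-coded numeric column(s);
# reference levels: female, de_novo, favorable, FALSE
.expand_covariate <- function(cohort, name) {
  cols <- list()
  if (name == "sex") {
    cols[["sex_male"]] <- ifelse(cohort$sex == "male", 1, 0)
  } else if (name == "aml_history") {
    cols[["aml_history_secondary"]] <- ifelse(cohort$aml_history == "secondary", 1, 0)
    cols[["aml_history_therapy_related"]] <- ifelse(cohort$aml_history == "therapy_related", 1, 0)
  } else if (name == "cytogenetic_risk") {
    cols[["cytogenetic_risk_intermediate"]] <- ifelse(cohort$cytogenetic_risk == "intermediate", 1, 0)
    cols[["cytogenetic_risk_adverse"]] <- ifelse(cohort$cytogenetic_risk == "adverse", 1, 0)
  } else if (name == "cv_risk_high") {
    cols[["cv_risk_high"]] <- ifelse(cohort$cv_risk_factor_count >= 2, 1, 0)
  } else if (name %in% names(cohort) && is.logical(cohort[[name]])) {
    cols[[name]] <- as.numeric(cohort[[name]])
  } else if (name %in% names(cohort) && is.numeric(cohort[[name]])) {
    cols[[name]] <- cohort[[name]]
  } else {
    stop("unknown covariate: ", name)
  }
  cols
}

# design matrix (no intercept column) for the given covariates;
# returns the matrix plus, per expanded column, its source covariate
ps_design <- function(cohort, covariates) {
  cols <- list()
  source <- character(0)
  for (nm in covariates) {
    ex <- .expand_covariate(cohort, nm)
    for (cn in names(ex)) {
      cols[[cn]] <- ex[[cn]]
      source[cn] <- nm
    }
  }
  X <- if (length(cols) == 0) {
    matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  } else {
    do.call(cbind, cols)
  }
  rownames(X) <- cohort$patient_id
  list(X = X, source = source)
}

# median (continuous) / most-frequent (indicator) imputation on the expanded design
.impute_design <- function(X) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (!any(miss)) next
    obs <- X[!miss, j]
    if (length(obs) == 0) stop("covariate column ", colnames(X)[j], " entirely missing")
    fill <- if (all(obs %in% c(0, 1))) as.numeric(mean(obs) >= 0.5) else stats::median(obs)
    X[miss, j] <- fill
  }
  X
}

#' Fit a propensity-score model
#'
#' Estimates the probability of carrying the exposure mutation given baseline
#' covariates by binomial logistic regression (iteratively reweighted least
#' squares run to a tight convergence tolerance, at most 100 iterations, so the
#' score equations hold to high precision at the optimum). Categorical
#' covariates are expanded to reference-coded indicators; continuous covariates
#' enter untransformed. Patients missing any model covariate are excluded
#' (complete-case default) unless `impute = TRUE`, which fills continuous
#' covariates with the median and indicators with the modal value.
#'
#' @param cohort cohort data frame.
#' @param covariates covariate names; see [default_ps_covariates()].
#' @param model `"model1"` (wildtype vs IDH2-mutated) or `"model2"` (wildtype
#'   vs pooled IDH1/2-mutated).
#' @param impute impute missing covariates instead of dropping the patient?
#' @return An object of class `ps_model` with the fitted coefficients, the
#'   per-patient propensity scores (`$ps`, named by patient id), exposure flags
#'   (`$exposed`), and convergence metadata.
#' @export
fit_propensity_model <- function(cohort, covariates = default_ps_covariates(),
                                 model = c("model2", "model1"), impute = FALSE) {
  model <- match.arg(model)
  ms <- model_subset(cohort, model)
  des <- ps_design(ms$cohort, covariates)
  X <- des$X
  y <- as.numeric(ms$exposed)

  if (impute) {
    X <- .impute_design(X)
    used <- rep(TRUE, nrow(X))
  } else {
    used <- stats::complete.cases(X)
  }
  Xu <- X[used, , drop = FALSE]
  yu <- y[used]
  ids <- ms$cohort$patient_id[used]

  if (sum(yu == 1) < 2 || sum(yu == 0) < 2)
    stop("propensity model needs at least 2 exposed and 2 control complete-case patients (",
         sum(yu == 1), " exposed, ", sum(yu == 0), " control after filtering)")
  if (ncol(Xu) > 0) {
    const <- apply(Xu, 2, function(v) length(unique(v)) == 1)
    if (any(const))
      stop("constant covariate(s) after complete-case filtering: ",
           paste(colnames(Xu)[const], collapse = ", "))
  }

  dat <- data.frame(.y = yu, Xu, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  beta <- stats::coef(fit)
  slopes <- beta[-1]
  if (any(!is.finite(beta)) || any(abs(slopes) > 15))
    stop("apparent separation in the propensity model (|coefficient| > 15 for ",
         paste(names(slopes)[abs(slopes) > 15 | !is.finite(slopes)], collapse = ", "),
         "); consider removing or coarsening that covariate")

  ps <- as.numeric(stats::fitted(fit))
  names(ps) <- ids
  exposed <- yu == 1
  names(exposed) <- ids

  structure(list(
    model_label = model,
    covariates = covariates,
    covariate_names = colnames(Xu),
    covariate_source = des$source,
    coefficients = beta,
    converged = fit$converged,
    n_used = length(yu),
    used_ids = ids,
    ps = ps,
    exposed = exposed
  ), class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat("Propensity model (", x$model_label, "): ", x$n_used, " patients, ",
      sum(x$exposed), " exposed\n", sep = "")
  cat("converged:", x$converged, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict propensity scores for new patients
#'
#' Inverse-logit of the fitted linear predictor; always strictly inside (0, 1).
#' Patients with a missing model covariate raise an error naming the patient
#' and the covariate.
#'
#' @param model a fitted [fit_propensity_model()] object.
#' @param cohort cohort data frame (any rows; exposure labels are not used).
#' @return Named numeric vector of probabilities.
#' @export
predict_ps <- function(model, cohort) {
  stopifnot(inherits(model, "ps_model"))
  des <- ps_design(cohort, model$covariates)
  X <- des$X[, model$covariate_names, drop = FALSE]
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    i <- miss[1, 1]; j <- miss[1, 2]
    stop("patient ", cohort$patient_id[i], " is missing covariate ",
         des$source[colnames(X)[j]])
  }
  eta <- drop(cbind(1, X) %*% model$coefficients)
  p <- stats::plogis(eta)
  names(p) <- cohort$patient_id
  p
}

#' Serialize / restore a propensity model as JSON
#'
#' @param model a `ps_model` object.
#' @param path file path to write (for `write_ps_model`) or read.
#' @return `write_ps_model` returns `path` invisibly; `read_ps_model` returns
#'   the restored `ps_model` (scores and ids included).
#' @export
write_ps_model <- function(model, path) {
  stopifnot(inherits(model, "ps_model"))
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)
  obj$covariate_source <- as.list(obj$covariate_source)
  obj$ps <- as.list(obj$ps)
  obj$exposed <- as.list(obj$exposed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ps_model
#' @export
read_ps_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$covariate_source <- unlist(obj$covariate_source)
  obj$ps <- unlist(obj$ps)
  obj$exposed <- unlist(obj$exposed)
  structure(obj, class = "ps_model")
}
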